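# Independent brute-force oracle for the two-state Gaussian HMM: evaluates
# the joint likelihood of every one of the 2^B state paths directly from
# the model definition (prior x emission x transition products) and sums.
# Feasible for B <= 8; deliberately shares no code with the package's
# scaled recursions.
oracleHMM <- function(values, params) {
    B <- length(values)
    prior <- hmmPrior(params)
    A <- hmmTransitions(params)
    mu <- emissionMeans(params)
    sg <- emissionSds(params)
    paths <- as.matrix(expand.grid(rep(list(1:2), B)))
    probs <- apply(paths, 1L, function(s) {
        p <- prior[s[1]] * dnorm(values[1], mu[s[1]], sg[s[1]])
        if (B > 1L) {
            for (b in 2:B)
                p <- p * A[s[b - 1L], s[b]] *
                    dnorm(values[b], mu[s[b]], sg[s[b]])
        }
        p
    })
    tot <- sum(probs)
    post <- matrix(0, B, 2L)
    for (b in seq_len(B))
        for (j in 1:2)
            post[b, j] <- sum(probs[paths[, b] == j]) / tot
    list(loglik = log(tot), post = post)
}

# A reusable well-separated test model (null N(0,5), enriched N(15,5),
# sticky transitions) mirroring control-subtracted data at typical depth.
testModel <- function(self = 0.95) {
    HMMParams(prior = c(0.5, 0.5),
              transitions = matrix(c(self, 1 - self, 1 - self, self), 2,
                                   byrow = TRUE),
              means = c(0, 15), sds = c(5, 5))
}
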