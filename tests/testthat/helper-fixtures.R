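## Shared fixtures and independent oracles, all built in code.

## simulate an ensemble and split it into (records, trajectories) lists
simPair <- function(id, params, nTrials, seed, nAgents = 6, duration = 360,
                    ...) {
  sims <- runEnsemble(simSettings(nAgents, id, params, duration = duration,
                                  ...), nTrials, seed = seed)
  list(recs = lapply(sims, function(x) x@orientation),
       trs = lapply(sims, function(x) x@trajectory),
       sims = sims)
}

## random orientation record + matching trajectory of given size
randomConfig <- function(Tn, N, seed) {
  set.seed(seed)
  tr <- trialTrajectory(matrix(runif(Tn * N, 0, 2 * pi), Tn, N),
                        frameRate = 7.5)
  rec <- orientationRecord(matrix(sample(c(-1L, 1L), Tn * N, replace = TRUE),
                                  Tn, N), dt = 1 / 7.5)
  list(rec = rec, tr = tr)
}

## brute-force joint log-probability of a state path under the symmetric HMM
## (uniform initial distribution); independent of the Viterbi implementation
pathLogProb <- function(obs, path, p, mu, sigma) {
  lp <- log(0.5) + dnorm(obs[1], mu * path[1], sigma, log = TRUE)
  for (t in seq_along(obs)[-1]) {
    lp <- lp + ifelse(path[t] == path[t - 1], log(1 - p), log(p)) +
      dnorm(obs[t], mu * path[t], sigma, log = TRUE)
  }
  lp
}

## exhaustive maximum over all 2^T paths
bestPathLogProb <- function(obs, p, mu, sigma) {
  Tn <- length(obs)
  best <- -Inf
  for (code in 0:(2^Tn - 1)) {
    path <- ifelse(bitwAnd(bitwShiftR(code, 0:(Tn - 1)), 1L) == 1L, 1L, -1L)
    lp <- pathLogProb(obs, path, p, mu, sigma)
    if (lp > best) best <- lp
  }
  best
}

## reference log-likelihood in plain R, built directly on the exported
## per-step intensity operations; independent of the compiled kernel
referenceLogLik <- function(rec, tr, model, params, dialect = "trace") {
  if (is.character(model)) model <- modelSpec(model)
  th <- thetaMatrix(tr)
  st <- stateMatrix(rec)
  ev <- eventMatrix(rec)
  Tn <- nrow(st)
  N <- ncol(st)
  th <- th[seq_len(Tn), , drop = FALSE]
  ll <- 0
  mems <- lapply(seq_len(N), function(i) emptyMemory(N, params@lambda0))
  for (t in seq_len(Tn - 1)) {
    for (i in seq_len(N)) {
      if (model@memory) {
        others <- setdiff(seq_len(N), i)
        if (model@zone %in% c("symmetric", "forward")) {
          inz <- others[inZone(th[t, i], st[t, i], th[t, others],
                               model@zone, params@R)]
        } else inz <- others
        negIn <- inz[st[t, inz] != st[t, i]]
        posIn <- inz[st[t, inz] == st[t, i]]
        turned <- t > 1 && ev[t - 1, i] == 1
        r <- intensityMemoryStep(model, params, mems[[i]], negIn, posIn,
                                 turned = turned, dialect = dialect)
        mems[[i]] <- r$mem
        lam <- r$lambda
      } else {
        cnt <- neighbourCounts(th[t, ], st[t, ], i, model@zone,
                               R = params@R, K = params@K)
        lam <- intensityMarkov(model, params, cnt)
      }
      p <- turnProbability(lam)
      lp <- if (ev[t, i] == 1) log(p) else log(1 - p)
      ll <- ll + max(lp, log(1e-12))
    }
  }
  ll
}
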