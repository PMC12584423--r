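# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) logsumexp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# half-Student-t log-density on x > 0 (location 0)
dhalft <- function(x, df, scale, log = FALSE) {
  ld <- ifelse(x < 0, -Inf, log(2) + stats::dt(x / scale, df = df, log = TRUE) - log(scale))
  if (log) ld else exp(ld)
}

qhalft <- function(p, df, scale) scale * stats::qt((1 + p) / 2, df = df)

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# deterministic per-chain seed derivation from a master seed (documented scheme)
chain_seed <- function(master, chain) {
  as.integer((as.numeric(master) + 104729 * as.numeric(chain)) %% 2147483629L)
}
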