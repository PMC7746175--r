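# Internal helpers shared across modules.

# Canonical movement order used everywhere: flexion, extension, left/right
# lateral bending, left/right rotation. Feature vectors, assay rows and CSV
# columns all follow this order.
MOVEMENTS <- c("F", "E", "Llb", "Rlb", "Lrt", "Rrt")

# The three anatomical axis pairs of the cervical spine.
MOVEMENT_PAIRS <- list(
  fe = c("F", "E"),
  lb = c("Llb", "Rlb"),
  rt = c("Lrt", "Rrt")
)

KIN_METRICS <- c("rom_deg", "rom_norm", "cv", "speed")

kinRowNames <- function() {
  as.vector(t(outer(MOVEMENTS, KIN_METRICS, paste, sep = ".")))
}

# Derive a reproducible child seed from a parent seed and an index path
# (e.g. patient number, repeat number). Lehmer-style multiply-add modulo
# 2^31 - 1; exact in double precision because all intermediates stay below
# 2^53. Order-independent reproducibility: each (seed, path) pair always
# yields the same stream regardless of when it is consumed.
seedStream <- function(seed, ...) {
  idx <- c(...)
  x <- (abs(as.numeric(seed)) + 1) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + abs(as.numeric(i)) + 1) %% 2147483647
  }
  as.integer(x %% 2147483645) + 1L
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# Truncated-normal draw via inverse-CDF so exactly n uniforms are consumed
# (keeps RNG streams stable no matter how often truncation binds).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Small deterministic text fingerprint for run manifests (polynomial hash
# mod 2^31 - 1, hex-encoded). Not cryptographic; only used to tie artifacts
# to the configuration that produced them.
textHash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
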