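# Physical constants and unit conversions used throughout.
# All beam arithmetic is done in photons, keV, mJ, fs, and micrometres.

# CODATA elementary charge; 1 keV in joule
.J_PER_KEV <- 1.602176634e-16

# 1 barn = 1e-24 cm^2 = 1e-16 um^2
.UM2_PER_BARN <- 1e-16

# FWHM of a Gaussian = sqrt(8 ln 2) * sigma
.FWHM_PER_SIGMA <- sqrt(8 * log(2))

# B-factor convention: B = 8 pi^2 <u^2>, so the atomic Gaussian has
# variance sigma^2 = B / (8 pi^2) (in A^2).
.b_to_sigma <- function(b) sqrt(b / (8 * pi^2))

.fwhm_to_sigma <- function(fwhm) fwhm / .FWHM_PER_SIGMA

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Seed handling: run `expr` under a fixed RNG seed and restore the caller's
# RNG state afterwards, so seeded simulations do not perturb the session.
.with_seed <- function(seed, expr) {
  if (!.is_number(seed) || seed != round(seed)) {
    .stopf("seed must be a single integer, got %s", deparse(seed))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
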