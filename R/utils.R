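#' The 11 cell-shape feature names, in canonical column order
#'
#' Order is fixed across the whole package: size features first, then
#' elongation, then irregularity descriptors.
#'
#' @return Character vector of length 11.
#' @export
shape_feature_names <- function() {
  c("area", "perimeter", "mean_radius", "min_feret", "max_feret",
    "aspect_ratio", "eccentricity", "compactness", "extent",
    "form_factor", "solidity")
}

#' Standard feature groupings used for group-wise classification
#'
#' Size, irregularity and elongation families of the 11 shape descriptors,
#' plus the \code{all} group.
#'
#' @return Named list of character vectors.
#' @export
shape_feature_groups <- function() {
  list(
    all          = shape_feature_names(),
    size         = c("area", "perimeter", "mean_radius", "min_feret", "max_feret"),
    irregularity = c("solidity", "extent", "form_factor"),
    elongation   = c("eccentricity", "aspect_ratio", "compactness")
  )
}

# Deterministic 31-bit stream seed from a master seed plus arbitrary labels.
# Polynomial string hash mod a prime below 2^31 keeps condition streams
# independent of each other and of condition order.
derive_seed <- function(master, ...) {
  p <- 2147480009
  h <- as.double(master %% p)
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(lab)))) {
      h <- (h * 31 + ch) %% p
    }
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so generators do not disturb user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
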