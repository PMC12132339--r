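#' @useDynLib fomopipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor cutree dist hclust kmeans median prcomp
#'   quantile rbinom rnorm runif sd var wilcox.test chisq.test predict rgamma
#' @importFrom utils head read.csv write.csv modifyList
NULL

# Run `expr` under a locally seeded RNG stream, restoring the caller's
# .Random.seed afterwards. All generators draw through this so a fixed
# SimConfig seed yields identical output regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unsigned angle between 2-D vectors, rowwise, in [0, pi].
angle_between <- function(u, v) {
  du <- sqrt(rowSums(u^2))
  dv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / pmax(du * dv, .Machine$double.eps)
  acos(pmin(pmax(cosang, -1), 1))
}

# Centered moving mean with shrinking windows at the edges.
moving_mean <- function(x, window) {
  if (window <= 1L) return(x)
  zoo::rollapply(x, width = window, FUN = mean, partial = TRUE, align = "center")
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}
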