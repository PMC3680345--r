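# Internal numerical helpers shared across modules.

# Linear predictors are clipped before exponentiation / inverse-logit so that
# extreme multivariate-normal parameter draws cannot overflow. Clips are rare
# under sane fits; callers may inspect the "censuscast.clip" condition count.
.LP_CLIP <- 30

clip_lp <- function(eta, warn = FALSE) {
  hi <- eta > .LP_CLIP
  lo <- eta < -.LP_CLIP
  if (any(hi | lo)) {
    if (warn) rlang::inform(
      sprintf("linear predictor clipped to [-%d, %d] for %d value(s)",
              .LP_CLIP, .LP_CLIP, sum(hi | lo)),
      class = "censuscast_clip"
    )
    eta[hi] <- .LP_CLIP
    eta[lo] <- -.LP_CLIP
  }
  eta
}

# Symmetrize a covariance matrix and, if it is not positive semidefinite,
# add a single jitter of 1e-8 * trace/dim before giving up.
ensure_psd <- function(V, label = "covariance") {
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  tol <- -1e-8 * max(1, abs(ev[1]))
  if (min(ev) < tol) {
    V <- V + diag(1e-8 * sum(diag(V)) / nrow(V), nrow(V))
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < tol) {
      stop(label, " matrix is not positive semidefinite", call. = FALSE)
    }
  }
  V
}

# Square-root factor L (d x d) of a PSD matrix such that L %*% z, z ~ N(0, I)
# has covariance V. Eigen-based so exactly-singular (including all-zero)
# covariances are handled.
psd_factor <- function(V) {
  V <- ensure_psd(V)
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

# One multivariate-normal draw using a precomputed factor.
mvn_draw <- function(mean, factor) {
  drop(mean + factor %*% stats::rnorm(length(mean)))
}

# Deterministic per-realization substream seed: changing the number of
# realizations M never reshuffles earlier realizations. Always < 2^31.
substream_seed <- function(master, r) {
  as.integer((as.double(master) %% 2147483397 + (r %% 2147483397) * 48271) %%
               2147483397) + 1L
}

# Draw a master seed when the caller did not fix one, using the ambient RNG so
# outer set.seed() still makes the whole computation reproducible.
master_seed <- function(seed = NULL) {
  if (is.null(seed)) seed <- sample.int(2147483397L, 1L)
  as.integer(seed)
}

assert_count_series <- function(x, what = "series") {
  if (length(x) == 0 || anyNA(x)) {
    stop(what, " must be a non-empty series without missing values", call. = FALSE)
  }
  if (any(x < 0) || any(x != round(x))) {
    stop(what, " must contain non-negative integer counts", call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Accept either a numeric vector of daily counts or a data frame with columns
# day (or date) and arrivals/count; returns a plain numeric vector indexed by
# day 1..T.
as_count_vector <- function(x, value_col = c("arrivals", "count", "census")) {
  if (is.data.frame(x)) {
    col <- intersect(value_col, names(x))
    if (length(col) == 0) {
      stop("data frame must have one of columns: ",
           paste(value_col, collapse = ", "), call. = FALSE)
    }
    x <- x[[col[1]]]
  }
  assert_count_series(x)
  as.numeric(x)
}
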