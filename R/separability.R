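#' Per-class sample statistics
#'
#' Extracts the DN vectors of a raster at labeled sample points and
#' summarizes each class by its band-mean vector and unbiased covariance.
#' Near-singular covariances (tiny samples on near-constant surfaces) are
#' ridge-regularized with `1e-6 * trace / dim` on the diagonal.
#'
#' @param raster an [mb_raster()].
#' @param samples a [point_set()] with a `class` column; every point must
#'   fall inside the raster.
#' @param min_n minimum sample count per class.
#' @return A list of `class_stats` objects (fields `class_name`, `n`,
#'   `mean`, `cov`).
#' @export
class_stats <- function(raster, samples, min_n = 5) {
  stopifnot(inherits(raster, "mb_raster"), !is.null(samples$class))
  d <- dim(raster$bands)
  rw <- map_to_row(raster, samples$y)
  cl <- map_to_col(raster, samples$x)
  if (any(rw < 1 | rw > d[1] | cl < 1 | cl > d[2])) {
    stop("sample point outside raster")
  }
  X <- vapply(seq_len(d[3]),
              function(k) raster$bands[, , k][cbind(rw, cl)],
              numeric(length(rw)))
  X <- matrix(X, ncol = d[3])
  out <- lapply(split(seq_len(nrow(X)), samples$class), function(idx) {
    if (length(idx) < min_n) {
      stop("class below minimum sample count (", min_n, ")")
    }
    Xi <- X[idx, , drop = FALSE]
    new_class_stats(samples$class[idx[1]], nrow(Xi), colMeans(Xi), cov(Xi))
  })
  unname(out)
}

new_class_stats <- function(class_name, n, mean, cov) {
  cov <- regularize_cov(as.matrix(cov))
  structure(list(class_name = class_name, n = n, mean = as.numeric(mean),
                 cov = cov), class = "class_stats")
}

regularize_cov <- function(S) {
  d <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    S <- S + diag(d) * (1e-6 * max(sum(diag(S)), 1e-3) / d)
  }
  S
}

#' Jeffries-Matusita distance between two Gaussian class models
#'
#' Computes the Bhattacharyya distance
#' \deqn{B = \frac18 (\mu_a-\mu_b)^T \left[\frac{\Sigma_a+\Sigma_b}{2}\right]^{-1}
#'   (\mu_a-\mu_b) + \frac12 \ln \frac{\det((\Sigma_a+\Sigma_b)/2)}
#'   {\sqrt{\det\Sigma_a \det\Sigma_b}}}
#' and returns `JM = 2 (1 - exp(-B))`, which ranges over \[0, 2\] and
#' saturates at 2 for fully separable classes.
#'
#' @param a,b `class_stats` objects (see [class_stats()]).
#' @return JM distance in \[0, 2\].
#' @export
jm_distance <- function(a, b) {
  stopifnot(inherits(a, "class_stats"), inherits(b, "class_stats"))
  Sa <- a$cov; Sb <- b$cov
  Sm <- (Sa + Sb) / 2
  ch <- tryCatch(chol(Sm), error = function(e) {
    stop("covariance not positive definite after regularization")
  })
  dmu <- a$mean - b$mean
  maha <- sum(backsolve(ch, dmu, transpose = TRUE)^2)
  ld_m <- 2 * sum(log(diag(ch)))
  ld_a <- determinant(Sa, logarithm = TRUE)$modulus
  ld_b <- determinant(Sb, logarithm = TRUE)$modulus
  B <- maha / 8 + 0.5 * (ld_m - 0.5 * (ld_a + ld_b))
  as.numeric(2 * (1 - exp(-B)))
}

#' Pairwise separability matrix with merge recommendations
#'
#' Computes the symmetric JM matrix over all class pairs and flags each
#' pair `good` (JM >= `good_min`, default 1.90), `poor` (JM <
#' `poor_max`, default 1.40) or `intermediate`.  Poorly separable pairs
#' are reported with a recommendation to merge them into one class for
#' pixel classification — the situation that arises when animals and
#' their attached shadows overlap in feature space.
#'
#' @param stats list of `class_stats`.
#' @param good_min,poor_max separability thresholds.
#' @return A list of class `separability_report`: `jm` (matrix), `flags`
#'   (data frame of pairs), `merge_recommendations` (list of class-name
#'   pairs).
#' @export
separability_matrix <- function(stats, good_min = 1.90, poor_max = 1.40) {
  stopifnot(length(stats) >= 2)
  nm <- vapply(stats, `[[`, character(1), "class_name")
  k <- length(stats)
  jm <- matrix(0, k, k, dimnames = list(nm, nm))
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- jm_distance(stats[[i]], stats[[j]])
    jm[i, j] <- jm[j, i] <- v
    flag <- if (v >= good_min) "good" else if (v < poor_max) "poor"
            else "intermediate"
    pairs[[length(pairs) + 1L]] <-
      data.frame(class_a = nm[i], class_b = nm[j], jm = v, flag = flag,
                 stringsAsFactors = FALSE)
  }
  flags <- do.call(rbind, pairs)
  poor <- flags[flags$flag == "poor", c("class_a", "class_b")]
  structure(list(jm = jm, flags = flags,
                 merge_recommendations =
                   lapply(seq_len(nrow(poor)),
                          function(i) c(poor$class_a[i], poor$class_b[i]))),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat("Jeffries-Matusita separability matrix:\n")
  print(round(x$jm, 3))
  if (length(x$merge_recommendations)) {
    cat("Poorly separable pairs (recommend merging):\n")
    for (p in x$merge_recommendations) {
      cat("  -", p[1], "+", p[2], "\n")
    }
  }
  invisible(x)
}
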