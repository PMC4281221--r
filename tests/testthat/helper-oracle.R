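## Independent brute-force oracle for the region-merging segmentation.
## Same heterogeneity criterion, merge schedule and tie rule as the
## package, but every quantity is recomputed from the pixel grid at every
## sweep, with no incremental bookkeeping.  Only usable on tiny rasters.

oracle_segment <- function(raster, params, thematic = NULL) {
  b <- raster$bands
  nr <- dim(b)[1]; nc <- dim(b)[2]; nbv <- dim(b)[3]
  w <- params$layer_weights
  sw <- params$shape_weight; cw <- params$compactness_weight
  thr <- params$scale^2
  if (is.null(thematic)) thematic <- matrix(0L, nr, nc)
  them <- matrix(as.integer(thematic), nr, nc)
  lab <- matrix(seq_len(nr * nc), nr, nc)  # column-major ids
  lab[is.na(them)] <- 0L
  them[is.na(them)] <- -1L

  region_info <- function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    n <- nrow(px)
    sds <- means <- numeric(nbv)
    for (k in seq_len(nbv)) {
      v <- b[, , k][lab == id]
      means[k] <- mean(v)
      sds[k] <- sqrt(max(0, mean(v^2) - mean(v)^2))
    }
    ## perimeter: pixel edges not shared with a same-region pixel
    per <- 0
    for (i in seq_len(n)) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- px[i, 1] + d[1]; c2 <- px[i, 2] + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || lab[r2, c2] != id) {
          per <- per + 1
        }
      }
    }
    list(n = n, sds = sds, per = per,
         bb = 2 * (diff(range(px[, 1])) + 1 + diff(range(px[, 2])) + 1))
  }

  shared_len <- function(a, bid) {
    px <- which(lab == a, arr.ind = TRUE)
    s <- 0
    for (i in seq_len(nrow(px))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- px[i, 1] + d[1]; c2 <- px[i, 2] + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            lab[r2, c2] == bid) {
          s <- s + 1
        }
      }
    }
    s
  }

  merge_cost <- function(a, bid) {
    A <- region_info(a); B <- region_info(bid)
    nm <- A$n + B$n
    vm <- numeric(nbv)
    for (k in seq_len(nbv)) {
      v <- b[, , k][lab == a | lab == bid]
      vm[k] <- sqrt(max(0, mean(v^2) - mean(v)^2))
    }
    dcolor <- sum(w * (nm * vm - A$n * A$sds - B$n * B$sds))
    shared <- shared_len(a, bid)
    lm <- A$per + B$per - 2 * shared
    px <- which(lab == a | lab == bid, arr.ind = TRUE)
    bbm <- 2 * (diff(range(px[, 1])) + 1 + diff(range(px[, 2])) + 1)
    dcmp <- nm * lm / sqrt(nm) - A$n * A$per / sqrt(A$n) -
      B$n * B$per / sqrt(B$n)
    dsmo <- nm * lm / bbm - A$n * A$per / A$bb - B$n * B$per / B$bb
    (1 - sw) * dcolor + sw * (cw * dcmp + (1 - cw) * dsmo)
  }

  neighbors_of <- function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    nbs <- integer(0)
    tv <- them[px[1, 1], px[1, 2]]
    for (i in seq_len(nrow(px))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- px[i, 1] + d[1]; c2 <- px[i, 2] + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            lab[r2, c2] != id && lab[r2, c2] > 0 &&
            them[r2, c2] == tv) {
          nbs <- c(nbs, lab[r2, c2])
        }
      }
    }
    sort(unique(nbs))
  }

  repeat {
    ids <- sort(unique(lab[lab > 0]))
    best <- setNames(rep(NA_integer_, length(ids)), ids)
    bcost <- setNames(rep(Inf, length(ids)), ids)
    for (id in ids) {
      for (nb in neighbors_of(id)) {
        cost <- merge_cost(id, nb)
        if (cost < bcost[[as.character(id)]]) {
          bcost[[as.character(id)]] <- cost
          best[[as.character(id)]] <- nb
        }
      }
    }
    merged_any <- FALSE
    for (id in ids) {
      if (!any(lab == id)) next
      bn <- best[[as.character(id)]]
      if (is.na(bn) || bn <= id) next
      if (!is.na(best[[as.character(bn)]]) &&
          best[[as.character(bn)]] == id &&
          bcost[[as.character(id)]] < thr) {
        lab[lab == bn] <- id
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  out <- matrix(0L, nr, nc)
  pos <- lab > 0
  out[pos] <- match(lab[pos], sort(unique(lab[pos])))
  out
}
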