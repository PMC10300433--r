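#' Angle of displacement vectors relative to a reference vector
#'
#' Signed mode: counterclockwise angle in the projection plane in [0, 360),
#' with 0 = parallel and 180 = antiparallel to the reference; the sign comes
#' from the cross-product component along the projection axis (left- vs
#' right-sided movement). Folded mode merges left and right to \[0, 180\].
#'
#' @param vec displacement vector(s): length-3 vector or (n x 3) matrix.
#' @param ref reference vector, length 3.
#' @param projection_plane `"xy"` (default), `"xz"`, `"yz"`, or `"none"` for
#'   the unsigned 3D angle (always in \[0, 180\]).
#' @param folded fold signed angles to \[0, 180\].
#' @return numeric vector of degrees; `NA` (with a warning) where the
#'   projected vector is zero.
#' @export
angle_to_reference <- function(vec, ref, projection_plane = "xy",
                               folded = FALSE) {
  vec <- matrix(as.numeric(unlist(vec)), ncol = 3)
  ref <- as.numeric(ref)
  if (projection_plane == "none") {
    nv <- sqrt(rowSums(vec^2)); nr <- sqrt(sum(ref^2))
    if (nr == 0) stop("zero reference vector")
    ang <- acos(pmin(pmax((vec %*% ref) / (nv * nr), -1), 1)) * 180 / pi
    ang[nv == 0] <- NA_real_
    if (anyNA(ang)) warning("zero displacement vector(s) flagged NA")
    return(as.numeric(ang))
  }
  ax <- switch(projection_plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3),
               stop("projection_plane must be xy, xz, yz or none"))
  v2 <- vec[, ax, drop = FALSE]
  r2 <- ref[ax]
  if (all(r2 == 0)) stop("reference vector vanishes in the projection plane")
  dotp <- v2[, 1] * r2[1] + v2[, 2] * r2[2]
  crossp <- r2[1] * v2[, 2] - r2[2] * v2[, 1]
  ang <- atan2(crossp, dotp) * 180 / pi
  ang <- ang %% 360
  zero <- v2[, 1] == 0 & v2[, 2] == 0
  ang[zero] <- NA_real_
  if (any(zero)) warning("vector(s) with zero projection flagged NA")
  if (folded) ang <- pmin(ang, 360 - ang)
  as.numeric(ang)
}

#' Rayleigh test of circular uniformity
#'
#' Mean resultant length R̄, Z = n R̄², and the small-sample-corrected
#' exponential p approximation. Folded samples (axial data on \[0, 180\]) are
#' tested on the doubled-angle circle by default.
#'
#' @param angles degrees.
#' @param folded set `TRUE` when `angles` are folded to \[0, 180\]; they are
#'   doubled before testing (the standard axial-data correction). Set
#'   `double_folded = FALSE` for the naive linear treatment.
#' @param double_folded apply the doubling transform to folded samples.
#' @return object of class `htest` with statistic R̄, parameter Z, p.value, n.
#' @export
rayleigh_test <- function(angles, folded = FALSE, double_folded = TRUE) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 4) stop("Rayleigh test needs n >= 4")
  if (n < 10) warning("Rayleigh test is unreliable below n = 10")
  a <- if (folded && double_folded) 2 * angles else angles
  th <- a * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  rbar <- sqrt(C^2 + S^2) / n
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(statistic = c(R_bar = rbar), parameter = c(Z = Z, n = n),
                 p.value = p,
                 method = paste0("Rayleigh test of uniformity",
                                 if (folded && double_folded)
                                   " (doubled folded angles)" else ""),
                 data.name = deparse(substitute(angles))),
            class = "htest")
}

# Watson's two-sample U^2 with midrank handling of ties
.watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b)
  N <- n + m
  val <- c(a, b)
  grp <- c(rep(1L, n), rep(2L, m))
  o <- order(val)
  val <- val[o]; grp <- grp[o]
  if (!anyDuplicated(val)) {
    # no ties: plain cumulative ecdf differences
    d <- cumsum(grp == 1L) / n - cumsum(grp == 2L) / m
    return((n * m / N^2) * (sum(d^2) - sum(d)^2 / N))
  }
  # cumulative ecdf differences, ties processed as one block
  d <- numeric(N)
  ca <- 0L; cb <- 0L
  i <- 1L
  while (i <= N) {
    j <- i
    while (j < N && val[j + 1] == val[i]) j <- j + 1L
    ca <- ca + sum(grp[i:j] == 1L)
    cb <- cb + sum(grp[i:j] == 2L)
    d[i:j] <- ca / n - cb / m
    i <- j + 1L
  }
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Watson's two-sample U² test of homogeneity
#'
#' Nonparametric test that two circular samples come from the same
#' distribution, from the pooled-sample rank formulation with midrank tie
#' handling. The p-value is computed by random relabeling permutation
#' (default; exact up to Monte Carlo error at typical sample sizes) or by the
#' standard asymptotic series.
#'
#' @param a,b samples of angles, degrees.
#' @param p_mode `"permutation"` or `"asymptotic"`.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for the permutation p.
#' @return object of class `htest` with statistic U², p.value, n, m.
#' @export
watson_u2_test <- function(a, b, p_mode = c("permutation", "asymptotic"),
                           n_perm = 999, seed = NULL) {
  p_mode <- match.arg(p_mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n <- length(a); m <- length(b)
  if (p_mode == "asymptotic" && (n < 8 || m < 8 || n + m < 17))
    stop("asymptotic mode needs n, m >= 8 and n + m >= 17")
  if (n < 2 || m < 2) stop("too few observations")
  u2 <- .watson_u2_stat(a, b)
  if (p_mode == "permutation") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    pool <- c(a, b)
    N <- n + m
    cnt <- 0L
    for (q in seq_len(n_perm)) {
      idx <- sample.int(N, n)
      if (.watson_u2_stat(pool[idx], pool[-idx]) >= u2) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  } else {
    k <- 1:25
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u2))
    p <- min(max(p, 0), 1)
  }
  structure(list(statistic = c(U2 = u2), parameter = c(n = n, m = m),
                 p.value = p,
                 method = paste0("Watson two-sample U2 test (", p_mode, ")"),
                 data.name = paste(deparse(substitute(a)), "vs",
                                   deparse(substitute(b)))),
            class = "htest")
}

#' Rose histogram (angular histogram) counts
#'
#' Equal-width bins over the declared angular range; counts sum to the sample
#' size.
#'
#' @param angles degrees.
#' @param n_bins number of bins (>= 2).
#' @param range angular range, default c(0, 360); use c(0, 180) for folded
#'   samples.
#' @return `data.frame` with bin_lo, bin_hi, count.
#' @export
rose_histogram <- function(angles, n_bins = 12, range = c(0, 360)) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  angles <- angles[!is.na(angles)]
  w <- diff(range) / n_bins
  k <- floor((angles - range[1]) / w)
  k[k == n_bins] <- n_bins - 1  # closed upper edge
  k <- pmin(pmax(k, 0), n_bins - 1)
  data.frame(bin_lo = range[1] + (0:(n_bins - 1)) * w,
             bin_hi = range[1] + (1:n_bins) * w,
             count = vapply(0:(n_bins - 1), function(q) sum(k == q),
                            integer(1)))
}
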