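#' Fit the null linear mixed model by spectral REML
#'
#' Model: `y = W a + u + e`, `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)`.
#' The eigendecomposition `K = U L U'` turns the GLS problem into
#' weighted least squares with weights `1 / (lambda_i + delta)`,
#' `delta = se2 / sg2`; the REML criterion is profiled over `log10(delta)`
#' on `[-5, 5]` by golden-section/Brent search.
#'
#' @param y numeric response (complete for included samples).
#' @param K positive semidefinite kinship matrix.
#' @param W fixed-effect design matrix (default intercept only).
#' @return A list of class `lmm_fit`: `delta`, `sg2`, `se2`, `loglik`
#'   (REML), `beta`, eigen pair `U`, `lambda`, and `flag_zero_variance`.
#' @export
fit_null <- function(y, K, W = NULL) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  W <- as.matrix(W)
  q <- ncol(W)
  stopifnot(nrow(K) == n, nrow(W) == n)
  if (stats::var(y) == 0) stop("constant response: variance components unidentifiable")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * sum(diag(K))) {
    stop("K is not positive semidefinite")
  }
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  ldet_WtW <- determinant(crossprod(W), logarithm = TRUE)$modulus
  if (!is.finite(ldet_WtW)) stop("singular fixed-effect design")

  reml <- function(log10_delta) {
    delta <- 10^log10_delta
    w <- 1 / (lambda + delta)
    WtWw <- crossprod(Ws, Ws * w)
    d <- determinant(WtWw, logarithm = TRUE)
    if (d$sign <= 0) return(list(ll = -Inf))
    beta <- solve(WtWw, crossprod(Ws, ys * w))
    r <- ys - drop(Ws %*% beta)
    rss <- sum(w * r^2)
    sg2 <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(2 * pi * sg2) + (n - q) +
                  sum(log(lambda + delta)) +
                  as.numeric(d$modulus) - as.numeric(ldet_WtW))
    list(ll = ll, beta = beta, sg2 = sg2, delta = delta)
  }
  opt <- stats::optimize(function(ld) reml(ld)$ll, c(-5, 5), maximum = TRUE,
                         tol = 1e-8)
  # guard against a maximum at the grid boundary beating the interior
  cand <- c(opt$maximum, -5, 5)
  lls <- vapply(cand, function(ld) reml(ld)$ll, 0)
  best <- reml(cand[which.max(lls)])
  flag <- FALSE
  if (best$sg2 < .Machine$double.eps * 100) {
    warning("estimated variance ~ 0; response nearly constant")
    flag <- TRUE
  }
  structure(list(delta = best$delta, sg2 = best$sg2,
                 se2 = best$delta * best$sg2, loglik = best$ll,
                 beta = drop(best$beta), U = U, lambda = lambda,
                 W = W, y = y, flag_zero_variance = flag),
            class = "lmm_fit")
}

## Direct dense REML log-likelihood at (delta, sg2 profiled): the oracle
## the spectral path is tested against.
reml_loglik_dense <- function(y, K, W, delta) {
  n <- length(y); q <- ncol(W)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(W) %*% Vi %*% W
  beta <- solve(XtViX, t(W) %*% Vi %*% y)
  r <- y - W %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  sg2 <- rss / (n - q)
  -0.5 * ((n - q) * log(2 * pi * sg2) + (n - q) +
          determinant(V, logarithm = TRUE)$modulus +
          determinant(XtViX, logarithm = TRUE)$modulus -
          determinant(crossprod(W), logarithm = TRUE)$modulus)
}

#' Mixed-model association scan
#'
#' Tests each variant with the null fit's variance ratio held fixed
#' (FaST-LMM's fast mode): in the spectral space, each marker joins the
#' fixed effects and its Wald test is computed by weighted least squares.
#' Missing dosages are mean-imputed; monomorphic variants are skipped.
#'
#' @param x `snp_data` (or dosage matrix with sample rows).
#' @param y phenotype vector aligned with the samples.
#' @param fit optional [fit_null()] result (computed from `K` otherwise).
#' @param K kinship matrix (required if `fit` missing).
#' @param W fixed-effect design (default intercept).
#' @return data.frame of class `gwas_result`: chrom, pos, maf, beta, se,
#'   stat, p, pve; attribute `lambda_gc` (genomic-control inflation) and
#'   `n_skipped` monomorphic count.
#' @export
lmm_scan <- function(x, y, fit = NULL, K = NULL, W = NULL) {
  D <- if (inherits(x, "snp_data")) x$dosage else x
  v <- if (inherits(x, "snp_data")) x$variants else
    data.frame(chrom = "un", pos = seq_len(ncol(D)))
  n <- length(y)
  if (is.null(fit)) {
    if (is.null(K)) stop("supply a null fit or a kinship matrix")
    fit <- fit_null(y, K, W)
  }
  U <- fit$U; w <- 1 / (fit$lambda + fit$delta)
  q <- ncol(fit$W)
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, fit$W)

  p_freq <- colMeans(D, na.rm = TRUE) / 2
  dos_var <- colMeans(D^2, na.rm = TRUE) - (2 * p_freq)^2
  mono <- is.nan(p_freq) | dos_var < 1e-12
  keep <- which(!mono)
  G <- D[, keep, drop = FALSE]
  cm <- colMeans(G, na.rm = TRUE)
  na_idx <- which(is.na(G))
  if (length(na_idx)) {
    G[na_idx] <- cm[((na_idx - 1L) %/% n) + 1L]
  }
  Gs <- crossprod(U, G)

  if (q == 1 && all(fit$W == 1)) {
    ones <- Ws[, 1]
    S11 <- sum(w * ones^2)
    S1y <- sum(w * ones * ys)
    Syy <- sum(w * ys^2)
    S1g <- drop(crossprod(Gs, w * ones))
    Sgg <- colSums(w * Gs^2)
    Sgy <- drop(crossprod(Gs, w * ys))
    det2 <- S11 * Sgg - S1g^2
    beta <- (S11 * Sgy - S1g * S1y) / det2
    # RSS = Syy - b' A^{-1} b for b = (S1y, Sgy)
    bAb <- (Sgg * S1y^2 - 2 * S1g * S1y * Sgy + S11 * Sgy^2) / det2
    rss <- pmax(Syy - bAb, 0)
    df <- n - 2L
    sigma2 <- rss / df
    se <- sqrt(sigma2 * S11 / det2)
  } else {
    m <- ncol(Gs)
    beta <- se <- rep(NA_real_, m)
    df <- n - q - 1L
    for (j in seq_len(m)) {
      Xj <- cbind(Ws, Gs[, j])
      f <- stats::lm.wfit(Xj, ys, w)
      rss <- sum(w * f$residuals^2)
      XtWX <- crossprod(Xj, Xj * w)
      cov_b <- solve(XtWX) * rss / df
      beta[j] <- f$coefficients[q + 1L]
      se[j] <- sqrt(cov_b[q + 1L, q + 1L])
    }
  }
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  maf <- pmin(p_freq[keep], 1 - p_freq[keep])
  pve_v <- pve(beta, p_freq[keep], stats::var(y))
  res <- data.frame(chrom = v$chrom[keep], pos = v$pos[keep],
                    maf = maf, beta = beta, se = se, stat = stat, p = p,
                    pve = pve_v, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gwas_result", "data.frame")
  attr(res, "lambda_gc") <- stats::median(stat^2, na.rm = TRUE) /
    stats::qchisq(0.5, 1)
  attr(res, "n_skipped") <- sum(mono)
  res
}

#' Genome-wide significance threshold
#'
#' `mode = "paper"` uses the `1/n` rule the array study applied;
#' `mode = "bonferroni"` is the conventional `0.05/n`.
#'
#' @param n_snps number of tested SNPs (>= 1).
#' @param mode `"paper"` or `"bonferroni"`.
#' @return p-value cutoff.
#' @export
significance_threshold <- function(n_snps, mode = c("paper", "bonferroni")) {
  mode <- match.arg(mode)
  stopifnot(n_snps >= 1)
  if (mode == "paper") 1 / n_snps else 0.05 / n_snps
}

#' Phenotypic variance explained by a single variant
#'
#' `PVE = beta^2 * 2 p (1 - p) / Var(y)`, clipped to `[0, 1)`. The
#' formula assumes Hardy-Weinberg dosage variance at ALT frequency `p`.
#'
#' @param beta estimated allele effect.
#' @param p ALT allele frequency.
#' @param var_y phenotypic variance.
#' @return PVE fraction(s).
#' @export
pve <- function(beta, p, var_y) {
  pmin(pmax(beta^2 * 2 * p * (1 - p) / var_y, 0), 1 - 1e-12)
}

#' Peak SNP per LD block
#'
#' Minimum-p variant within each block interval; ties broken by larger
#' `|beta|`, then by position.
#'
#' @param results a `gwas_result` data.frame.
#' @param blocks data.frame with `chrom`, `start`, `end` (bp intervals).
#' @return One row of `results` per block (with a `block` index column);
#'   blocks containing no tested SNP are omitted.
#' @export
peak_snps <- function(results, blocks) {
  out <- list()
  for (b in seq_len(nrow(blocks))) {
    inb <- which(results$chrom == blocks$chrom[b] &
                 results$pos >= blocks$start[b] &
                 results$pos <= blocks$end[b])
    if (!length(inb)) next
    r <- results[inb, , drop = FALSE]
    r <- r[order(r$p, -abs(r$beta), r$pos), , drop = FALSE]
    row <- r[1, , drop = FALSE]
    row$block <- b
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(results[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
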