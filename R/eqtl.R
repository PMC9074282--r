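#' Residualize delta-expression on line-level covariates
#'
#' Fixed-effect adjustment of each transcript's per-line delta-expression on
#' the supplied covariates (Wolbachia status, inversion indicators, top
#' genotype principal components, ...). Collinear covariate columns are
#' dropped (recorded in `attr(, "dropped")`); the intercept is always
#' included, so adding a constant to the phenotype leaves the residuals
#' unchanged.
#'
#' @param delta lines x transcripts matrix.
#' @param covariates lines x k numeric matrix or data.frame, rows aligned
#'   with (or named by) the lines of `delta`.
#' @return matrix of residuals, same shape as `delta`.
#' @export
adjust_covariates <- function(delta, covariates) {
  covariates <- as.matrix(covariates)
  if (!is.null(rownames(covariates)) && !is.null(rownames(delta))) {
    if (!setequal(rownames(covariates), rownames(delta)))
      stop("covariate lines do not match phenotype lines")
    covariates <- covariates[rownames(delta), , drop = FALSE]
  } else if (nrow(covariates) != nrow(delta)) {
    stop("covariates must have one row per line")
  }
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
  res <- qr.resid(qx, delta)
  dimnames(res) <- dimnames(delta)
  attr(res, "dropped") <- dropped
  res
}

#' Principal components of the genotype matrix
#'
#' PCA of the column-centered lines x variants matrix via singular value
#' decomposition, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive), so scores are invariant to
#' variant order and reproducible across runs.
#'
#' @param geno a `genotype_matrix` or a lines x variants numeric matrix.
#' @param k number of components (< number of lines).
#' @return lines x k score matrix, columns PC1..PCk; proportion of variance
#'   in `attr(, "varprop")`.
#' @export
genotype_pca <- function(geno, k = 10) {
  G <- if (inherits(geno, "genotype_matrix")) geno$geno else geno
  if (k >= nrow(G)) stop("k must be smaller than the number of lines")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sv <- La.svd(Gc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$vt[j, ]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% diag(flip, k, k)
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  attr(scores, "varprop") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  scores
}

## vectorized simple-regression scan of one or more phenotypes on genotype
## dosage (coded 0/1 after halving the 0/2 calls); returns list of matrices
scan_core <- function(Y, G) {
  # Y: lines x phenos; G: lines x variants (0/2)
  n <- nrow(Y)
  X <- G / 2
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sxx <- colSums(Xc^2)
  sxy <- crossprod(Xc, Yc)                    # variants x phenos
  syy <- colSums(Yc^2)
  beta <- sxy / sxx
  rss <- outer(rep(1, length(sxx)), syy) - beta * sxy
  df <- n - 2
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  list(beta = beta, t = tstat, p = p)
}

#' Single-variant association scan
#'
#' Per variant, a simple linear regression of the (adjusted) delta-expression
#' phenotype on genotype dosage (0/2 calls halved to 0/1, so the slope is the
#' effect of the homozygous substitution). Variants with fewer than
#' `min_class` lines in either genotype class are skipped (NA statistics).
#'
#' @param pheno numeric phenotype vector, one value per line.
#' @param geno a `genotype_matrix` with matching lines.
#' @param min_class minimum lines per genotype class.
#' @return data.frame variant, beta, t, p.
#' @export
eqtl_scan <- function(pheno, geno, min_class = 3) {
  G <- geno$geno
  if (!is.null(names(pheno))) G <- G[names(pheno), , drop = FALSE]
  if (var(pheno) == 0) {
    warning("phenotype has zero variance; all p set to 1")
    return(data.frame(variant = colnames(G), beta = 0, t = 0, p = 1))
  }
  n2 <- colSums(G == 2); n0 <- nrow(G) - n2
  ok <- pmin(n0, n2) >= min_class
  out <- data.frame(variant = colnames(G), beta = NA_real_, t = NA_real_,
                    p = NA_real_)
  if (any(ok)) {
    st <- scan_core(matrix(pheno), G[, ok, drop = FALSE])
    out$beta[ok] <- st$beta[, 1]
    out$t[ok] <- st$t[, 1]
    out$p[ok] <- st$p[, 1]
  }
  out
}

#' Permutation-based empirical FDR threshold for an eQTL scan
#'
#' Shuffles the phenotype's line labels jointly across variants (preserving
#' genotype LD) `n_perm` times. For candidate thresholds t at the observed
#' p-values, the empirical FDR is the mean number of permutation p-values
#' at or below t divided by the number of observed p-values at or below t;
#' the returned threshold is the largest t with empirical FDR <= `fdr`
#' (0 when none qualifies).
#'
#' @inheritParams eqtl_scan
#' @param n_perm number of permutations (>= 1).
#' @param fdr target false discovery rate.
#' @param seed optional integer seed for the shuffles.
#' @return list: `threshold`, `discoveries` (data.frame of variants with
#'   observed p <= threshold), `scan` (full observed scan), `n_perm`, `fdr`.
#' @export
permutation_fdr <- function(pheno, geno, n_perm = 100, fdr = 0.05,
                            seed = NULL, min_class = 3) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- eqtl_scan(pheno, geno, min_class = min_class)
  keep <- !is.na(obs$p)
  G <- geno$geno
  if (!is.null(names(pheno))) G <- G[names(pheno), , drop = FALSE]
  G <- G[, keep, drop = FALSE]
  n <- length(pheno)
  perm_y <- vapply(seq_len(n_perm), function(b) pheno[sample.int(n)],
                   numeric(n))
  perm_p <- scan_core(perm_y, G)$p
  cand <- sort(unique(obs$p[keep]))
  sp_obs <- sort(obs$p[keep])
  sp_perm <- sort(as.vector(perm_p))
  n_obs <- findInterval(cand, sp_obs)
  n_null <- findInterval(cand, sp_perm) / n_perm
  efdr <- n_null / n_obs
  ok <- which(efdr <= fdr)
  threshold <- if (length(ok)) cand[max(ok)] else 0
  disc <- obs[keep & obs$p <= threshold, , drop = FALSE]
  disc <- disc[order(disc$p, disc$variant), , drop = FALSE]
  rownames(disc) <- NULL
  list(threshold = threshold, discoveries = disc, scan = obs,
       n_perm = n_perm, fdr = fdr)
}

#' Forward conditional selection of independent eQTLs
#'
#' Candidates (the empirical-FDR discoveries) are added in order of marginal
#' p-value (ties broken by variant id) to an additive multiple-regression
#' model; a candidate is kept iff its conditional p-value in the model is at
#' most `conditional_p_max`. Exact duplicates of already-kept genotype
#' columns are skipped.
#'
#' @inheritParams eqtl_scan
#' @param discoveries data.frame with columns `variant` and `p` (marginal).
#' @param conditional_p_max conditional p-value cutoff.
#' @return data.frame variant, beta, p_marginal, p_conditional in order of
#'   addition (zero rows when nothing selected).
#' @export
forward_select <- function(pheno, geno, discoveries,
                           conditional_p_max = 1e-5) {
  empty <- data.frame(variant = character(0), beta = numeric(0),
                      p_marginal = numeric(0), p_conditional = numeric(0))
  if (!nrow(discoveries)) return(empty)
  G <- geno$geno
  if (!is.null(names(pheno))) G <- G[names(pheno), , drop = FALSE]
  ord <- order(discoveries$p, discoveries$variant)
  cand <- discoveries[ord, , drop = FALSE]
  kept <- empty
  X <- matrix(1, length(pheno), 1)
  for (i in seq_len(nrow(cand))) {
    g <- G[, cand$variant[i]] / 2
    Xtry <- cbind(X, g)
    qx <- qr(Xtry)
    if (qx$rank < ncol(Xtry)) next     # collinear with kept set: skip
    cf <- qr.coef(qx, pheno)
    res <- qr.resid(qx, pheno)
    df <- length(pheno) - ncol(Xtry)
    if (df <= 0) break
    s2 <- sum(res^2) / df
    xtx_inv <- chol2inv(qr.R(qx))
    se <- sqrt(s2 * xtx_inv[ncol(Xtry), ncol(Xtry)])
    pcond <- 2 * pt(-abs(cf[length(cf)] / se), df)
    if (pcond <= conditional_p_max) {
      X <- Xtry
      kept <- rbind(kept, data.frame(variant = cand$variant[i],
                                     beta = unname(cf[length(cf)]),
                                     p_marginal = cand$p[i],
                                     p_conditional = pcond))
    }
  }
  kept
}

#' Classify a variant as cis or trans to a gene
#'
#' cis iff the variant lies on the gene's chromosome within
#' `[start - window, end + window]` (1-based inclusive; "within 1 kb" of the
#' gene body includes exactly 1,000 bp); trans otherwise, including any
#' variant on a different chromosome.
#'
#' @param variant_chrom,variant_pos variant coordinates (1-based).
#' @param gene one-row data.frame (or list) with chrom, start, end.
#' @param window flanking window in bp.
#' @return "cis" or "trans".
#' @export
classify_cis_trans <- function(variant_chrom, variant_pos, gene,
                               window = 1000) {
  if (gene$start > gene$end) stop("malformed gene coordinates: start > end")
  if (variant_chrom != gene$chrom) return("trans")
  if (variant_pos >= gene$start - window && variant_pos <= gene$end + window)
    "cis" else "trans"
}

#' Genes a variant is cis to
#'
#' All genes whose gene body extended by `window` bp on both sides contains
#' the variant; an empty result means the variant is intergenic (more than
#' `window` bp from any gene body).
#'
#' @param variant_chrom,variant_pos variant coordinates.
#' @param annotation data.frame gene, chrom, start, end (1-based inclusive).
#' @param window flanking window in bp.
#' @return character vector of gene ids (possibly empty).
#' @export
annotate_cis_genes <- function(variant_chrom, variant_pos, annotation,
                               window = 1000) {
  hit <- annotation$chrom == variant_chrom &
    variant_pos >= annotation$start - window &
    variant_pos <= annotation$end + window
  annotation$gene[hit]
}

#' Map response eQTLs for a set of transcripts
#'
#' Full per-transcript pipeline: covariate adjustment, single-variant scan,
#' permutation-based empirical FDR threshold, forward conditional selection,
#' and cis/trans annotation of the selected variants relative to the focal
#' gene plus the list of genes each variant is cis to.
#'
#' @param delta lines x transcripts delta-expression matrix.
#' @param geno a `genotype_matrix`.
#' @param covariates lines x k covariate table (see [adjust_covariates()]).
#' @param annotation gene annotation data.frame (gene, chrom, start, end).
#' @param n_perm,fdr,conditional_p_max,window,min_class stage parameters.
#' @param seed integer seed (one independent shuffle stream per transcript).
#' @return data.frame, one row per selected eQTL: transcript, variant, beta,
#'   p_marginal, p_conditional, threshold, cis_trans (relative to the focal
#'   gene), cis_genes (comma-separated, "intergenic" when none).
#' @export
map_eqtls <- function(delta, geno, covariates, annotation, n_perm = 100,
                      fdr = 0.05, conditional_p_max = 1e-5, window = 1000,
                      min_class = 3, seed = 1L) {
  adj <- adjust_covariates(delta, covariates)
  vtab <- geno$variants
  out <- NULL
  for (j in seq_len(ncol(adj))) {
    tx <- colnames(adj)[j]
    pheno <- setNames(adj[, j], rownames(adj))
    pf <- permutation_fdr(pheno, geno, n_perm = n_perm, fdr = fdr,
                          seed = stage_seed(seed, tx), min_class = min_class)
    sel <- forward_select(pheno, geno, pf$discoveries,
                          conditional_p_max = conditional_p_max)
    if (!nrow(sel)) next
    focal <- annotation[annotation$gene == tx, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      vr <- vtab[vtab$variant == sel$variant[k], ]
      ct <- if (nrow(focal) == 1)
        classify_cis_trans(vr$chrom, vr$pos, focal, window) else NA_character_
      cis <- annotate_cis_genes(vr$chrom, vr$pos, annotation, window)
      out <- rbind(out, data.frame(
        transcript = tx, variant = sel$variant[k], beta = sel$beta[k],
        p_marginal = sel$p_marginal[k], p_conditional = sel$p_conditional[k],
        threshold = pf$threshold, cis_trans = ct,
        cis_genes = if (length(cis)) paste(cis, collapse = ",")
                    else "intergenic"))
    }
  }
  if (is.null(out))
    out <- data.frame(transcript = character(0), variant = character(0),
                      beta = numeric(0), p_marginal = numeric(0),
                      p_conditional = numeric(0), threshold = numeric(0),
                      cis_trans = character(0), cis_genes = character(0))
  rownames(out) <- NULL
  out
}
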