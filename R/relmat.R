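## Relationship matrices carry their provenance as attributes so downstream
## stages (model fitting, reports) can label output without extra plumbing.
new_relmat <- function(values, kind, source, snp_class = "all") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("relationship matrix must be labeled")
  colnames(values) <- rownames(values)
  attr(values, "kind") <- match.arg(kind, c("additive", "dominance"))
  attr(values, "source") <- match.arg(source, c("pedigree", "marker"))
  attr(values, "snp_class") <- snp_class
  class(values) <- c("px_relmat", class(values))
  values
}

#' @export
print.px_relmat <- function(x, ...) {
  cat(sprintf("<px_relmat> %s (%s-derived), %d individuals, SNP class: %s\n",
              attr(x, "kind"), attr(x, "source"), nrow(x), attr(x, "snp_class")))
  n <- min(6L, nrow(x))
  print(round(unclass(x)[seq_len(n), seq_len(n), drop = FALSE], 4), ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows/cols\n", nrow(x) - n))
  invisible(x)
}

geno_freq <- function(dosage) {
  colMeans(dosage, na.rm = TRUE) / 2
}

#' Filter SNPs and individuals on MAF and missingness
#'
#' Applies the marker quality-control rules used before building genomic
#' relationship matrices: individuals with too much missing data are dropped
#' first, then SNPs failing the minor-allele-frequency or per-SNP missingness
#' thresholds are removed. Allele frequencies are recomputed from the retained
#' individuals.
#'
#' @param dosage numeric matrix, individuals x SNPs, allele dosages in
#'   \{0,1,2\} with `NA` for missing calls; rownames are individual ids,
#'   colnames SNP ids.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param max_snp_missing maximum per-SNP missing fraction (default 0.2).
#' @param max_ind_missing maximum per-individual missing fraction (default 0.4).
#' @return list with `dosage` (filtered matrix) and `report`, a list counting
#'   removals per rule (`n_ind_removed`, `n_snp_maf`, `n_snp_missing`,
#'   `removed_individuals`, `removed_snps`).
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 0, 0, 0), nrow = 4,
#'             dimnames = list(paste0("i", 1:4), c("s1", "s2")))
#' filter_snps(g, maf_min = 0.01)$report$n_snp_maf  # s2 is monomorphic
#' @export
filter_snps <- function(dosage, maf_min = 0.01, max_snp_missing = 0.2,
                        max_ind_missing = 0.4) {
  stopifnot(is.matrix(dosage))
  for (th in c(maf_min, max_snp_missing, max_ind_missing)) {
    if (!is.finite(th) || th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  }
  ind_miss <- rowMeans(is.na(dosage))
  keep_ind <- ind_miss <= max_ind_missing
  removed_ind <- rownames(dosage)[!keep_ind]
  dosage <- dosage[keep_ind, , drop = FALSE]

  p <- geno_freq(dosage)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0          # fully-missing column: fails the MAF rule too
  snp_miss <- colMeans(is.na(dosage))
  fail_maf <- maf < maf_min
  fail_miss <- snp_miss > max_snp_missing
  keep_snp <- !(fail_maf | fail_miss)
  removed_snp <- colnames(dosage)[!keep_snp]
  out <- dosage[, keep_snp, drop = FALSE]
  if (ncol(out) == 0L) stop("all SNPs removed by filtering")
  list(dosage = out,
       report = list(n_ind_removed = sum(!keep_ind),
                     n_snp_maf = sum(fail_maf),
                     n_snp_missing = sum(fail_miss & !fail_maf),
                     removed_individuals = removed_ind,
                     removed_snps = removed_snp))
}

#' Impute missing genotype dosages
#'
#' Mean imputation replaces each missing call with twice the observed allele
#' frequency of its SNP. EM imputation iterates conditional-mean prediction of
#' the missing entries from a shrunken marker covariance until the imputed
#' values stabilise; observed entries are never altered.
#'
#' @param dosage numeric dosage matrix with `NA` for missing calls.
#' @param method `"mean"` (default) or `"em"`.
#' @param tol relative-change convergence tolerance for EM.
#' @param max_iter maximum EM sweeps.
#' @return a complete real-valued dosage matrix.
#' @export
impute_missing <- function(dosage, method = c("mean", "em"),
                           tol = 1e-6, max_iter = 100L) {
  method <- match.arg(method)
  miss <- is.na(dosage)
  if (!any(miss)) return(dosage)
  if (any(colSums(!miss) == 0L))
    stop("fully missing SNP: filter before imputing")
  p <- geno_freq(dosage)
  out <- dosage
  out[miss] <- rep(2 * p, each = nrow(dosage))[miss]
  if (method == "mean") return(out)

  ## EM as iterated low-rank conditional mean: the centered dosage matrix is
  ## approximated by its leading singular subspace (capturing family/relatedness
  ## structure), missing cells are replaced by the reconstruction, and the
  ## subspace is re-estimated until the imputed values stabilise.
  rank <- max(1L, min(nrow(out) - 1L, ncol(out) - 1L, 20L))
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(out)
    w <- sweep(out, 2, mu, "-")
    sv <- svd(w, nu = rank, nv = rank)
    d <- sv$d[seq_len(rank)]
    ## shrink singular values (soft threshold at the trailing level) to avoid
    ## propagating noise into the imputed cells
    thr <- if (length(sv$d) > rank) sv$d[rank + 1L] else 0
    fit <- sv$u %*% (pmax(d - thr, 0) * t(sv$v))
    new <- out
    new[miss] <- pmin(pmax((fit + rep(mu, each = nrow(out)))[miss], 0), 2)
    delta <- max(abs(new[miss] - out[miss])) / (max(abs(out[miss])) + 1e-12)
    out <- new
    if (delta < tol) break
  }
  out
}

#' Realized additive genomic relationship matrix (VanRaden)
#'
#' Centers each SNP column by twice its allele frequency and scales the
#' cross-product by twice the summed heterozygosity:
#' \deqn{G = W W' / (2 \sum_m p_m (1 - p_m)), \quad W_{im} = x_{im} - 2 p_m.}
#' Frequencies are computed from the supplied (analyzed) sample.
#'
#' @param dosage complete numeric dosage matrix (individuals x SNPs);
#'   fractional imputed dosages are allowed.
#' @param snp_class label recorded on the result (e.g. `"intergenic"`).
#' @return a `px_relmat` additive marker relationship matrix.
#' @export
G_additive <- function(dosage, snp_class = "all") {
  stopifnot(is.matrix(dosage))
  if (anyNA(dosage)) stop("dosage must be complete; impute first")
  p <- colMeans(dosage) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: additive G undefined")
  w <- sweep(dosage, 2, 2 * p, "-")
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2
  new_relmat(g, "additive", "marker", snp_class)
}

## Three-point dominance coding of Vitezica et al., linearly interpolated for
## fractional (imputed) dosages: h(0) = -2q^2, h(1) = 2pq, h(2) = -2p^2.
dominance_coding <- function(dosage, p) {
  q <- 1 - p
  h0 <- -2 * q^2
  h1 <- 2 * p * q
  h2 <- -2 * p^2
  n <- nrow(dosage)
  lo <- pmin(pmax(dosage, 0), 2)
  seg1 <- pmin(lo, 1)        # weight within [0,1]
  seg2 <- pmax(lo - 1, 0)    # weight within [1,2]
  H0 <- matrix(h0, n, length(p), byrow = TRUE)
  H1 <- matrix(h1, n, length(p), byrow = TRUE)
  H2 <- matrix(h2, n, length(p), byrow = TRUE)
  H0 + (H1 - H0) * seg1 + (H2 - H1) * seg2
}

#' Realized dominance genomic relationship matrix (Vitezica)
#'
#' Uses the mean-zero-under-HWE dominance coding per SNP
#' (\eqn{-2q^2, 2pq, -2p^2} for dosages 0, 1, 2) and scales by
#' \eqn{\sum_m (2 p_m q_m)^2}.
#'
#' @inheritParams G_additive
#' @return a `px_relmat` dominance marker relationship matrix.
#' @export
G_dominance <- function(dosage, snp_class = "all") {
  stopifnot(is.matrix(dosage))
  if (anyNA(dosage)) stop("dosage must be complete; impute first")
  p <- colMeans(dosage) / 2
  denom <- sum((2 * p * (1 - p))^2)
  if (denom <= 0) stop("all SNPs monomorphic: dominance G undefined")
  h <- dominance_coding(dosage, p)
  dimnames(h) <- dimnames(dosage)
  g <- tcrossprod(h) / denom
  g <- (g + t(g)) / 2
  new_relmat(g, "dominance", "marker", snp_class)
}

## Topological order of a pedigree: parents before offspring.
ped_sort <- function(ped) {
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate ids in pedigree")
  mo <- as.character(ped$mother); fa <- as.character(ped$father)
  mo[mo %in% c("", "0", "NA")] <- NA; fa[fa %in% c("", "0", "NA")] <- NA
  unknown <- unique(c(mo[!is.na(mo) & !(mo %in% ids)],
                      fa[!is.na(fa) & !(fa %in% ids)]))
  if (length(unknown))
    stop("pedigree refers to unknown parent(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  placed <- logical(length(ids)); names(placed) <- ids
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(mo) | placed[match(mo, ids)]) &
      (is.na(fa) | placed[match(fa, ids)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle")
  data.frame(id = ids[order_out], mother = mo[order_out], father = fa[order_out],
             stringsAsFactors = FALSE)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix A by the standard recursion:
#' \eqn{a_{ii} = 1 + 0.5 a_{fm}} and \eqn{a_{ij} = 0.5 (a_{jf} + a_{jm})}
#' with missing parents contributing zero.
#'
#' @param ped data.frame with character columns `id`, `mother`, `father`
#'   (`NA`, `""` or `"0"` for unknown parents). Any order; sorted internally.
#' @return a `px_relmat` additive pedigree relationship matrix in the input
#'   id order.
#' @examples
#' ped <- data.frame(id = c("f", "m", "o"), mother = c(NA, NA, "m"),
#'                   father = c(NA, NA, "f"))
#' A_additive(ped)["f", "o"]  # 0.5
#' @export
A_additive <- function(ped) {
  ps <- ped_sort(ped)
  n <- nrow(ps)
  a <- matrix(0, n, n, dimnames = list(ps$id, ps$id))
  mi <- match(ps$mother, ps$id); fi <- match(ps$father, ps$id)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (!is.na(mi[i])) v <- v + a[j, mi[i]]
      if (!is.na(fi[i])) v <- v + a[j, fi[i]]
      a[i, j] <- a[j, i] <- 0.5 * v
    }
    f_im <- if (!is.na(mi[i]) && !is.na(fi[i])) 0.5 * a[mi[i], fi[i]] else 0
    a[i, i] <- 1 + f_im
  }
  orig <- as.character(ped$id)
  new_relmat(a[orig, orig, drop = FALSE], "additive", "pedigree")
}

#' Pedigree dominance relationship matrix
#'
#' For individuals i, j with parents (fi, mi), (fj, mj):
#' \eqn{d_{ij} = 0.25 (a_{fi,fj} a_{mi,mj} + a_{fi,mj} a_{mi,fj})}, with any
#' missing parent contributing zero; diagonal entries are 1.
#'
#' @inheritParams A_additive
#' @return a `px_relmat` dominance pedigree relationship matrix.
#' @export
A_dominance <- function(ped) {
  a <- A_additive(ped)
  ids <- rownames(a)
  mo <- as.character(ped$mother)[match(ids, as.character(ped$id))]
  fa <- as.character(ped$father)[match(ids, as.character(ped$id))]
  mo[mo %in% c("", "0", "NA")] <- NA; fa[fa %in% c("", "0", "NA")] <- NA
  n <- length(ids)
  look <- function(x, y) {
    if (is.na(x) || is.na(y)) 0 else a[x, y]
  }
  d <- diag(1, n)
  dimnames(d) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- 0.25 *
        (look(fa[i], fa[j]) * look(mo[i], mo[j]) +
         look(fa[i], mo[j]) * look(mo[i], fa[j]))
    }
  }
  new_relmat(d, "dominance", "pedigree")
}

#' Pearson correlation between two relationship matrices
#'
#' Correlates the upper triangles (diagonal included) of two matrices after
#' aligning them on the shared id set.
#'
#' @param m1,m2 labeled symmetric matrices over the same individuals.
#' @return a single correlation coefficient.
#' @export
matrix_correlation <- function(m1, m2) {
  if (!setequal(rownames(m1), rownames(m2)))
    stop("relationship matrices cover different individuals")
  ids <- rownames(m1)
  m2 <- m2[ids, ids]
  ut <- upper.tri(m1, diag = TRUE)
  stats::cor(m1[ut], m2[ut])
}

#' Subset a genotype matrix by SNP annotation category
#'
#' @param dosage dosage matrix (columns = SNPs).
#' @param annotation data.frame with columns `snp_id` and `category`.
#' @param category category to retain.
#' @return list with `dosage` (restricted columns) and `class_report`, the
#'   observed fractions of dosage codes 0/1/2 in the subset.
#' @export
subset_by_annotation <- function(dosage, annotation, category) {
  stopifnot(all(c("snp_id", "category") %in% names(annotation)))
  if (anyDuplicated(annotation$snp_id)) stop("annotation categories must be disjoint per SNP")
  keep <- annotation$snp_id[annotation$category == category]
  keep <- intersect(colnames(dosage), keep)
  if (length(keep) == 0L) stop("no SNPs in category '", category, "'")
  sub <- dosage[, keep, drop = FALSE]
  tab <- table(factor(round(sub[!is.na(sub)]), levels = 0:2))
  list(dosage = sub,
       class_report = as.numeric(tab / sum(tab)))
}
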