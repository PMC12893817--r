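#' Principal component analysis of SV genotypes
#'
#' Genotypes coded 0/1/2 are mean-imputed per site, centred by 2p and
#' scaled by sqrt(2p(1-p)) (the standardized-genotype relationship
#' matrix convention), then decomposed by SVD. Zero-variance sites are
#' dropped.
#'
#' @param gm an [sv_genotypes()] object.
#' @param n_components number of components to return.
#' @return list with `coords` (accessions x components), `explained`
#'   (variance fractions, non-increasing), `sdev`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  d <- gt_dosage(gm)
  # per-site mean imputation
  mu <- rowMeans(d, na.rm = TRUE)
  for (i in seq_len(nrow(d))) d[i, is.na(d[i, ])] <- mu[i]
  p <- rowMeans(d) / 2
  keep <- p > 0 & p < 1
  if (!any(keep))
    stop("zero-variance genotype matrix: no polymorphic sites")
  x <- (d[keep, , drop = FALSE] - 2 * p[keep]) /
    sqrt(2 * p[keep] * (1 - p[keep]))
  sv <- svd(t(x))
  n_components <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- gm$accessions
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       sdev = sv$d[seq_len(n_components)])
}

#' Allele-sharing distance matrix between accessions
#'
#' 1 - IBS over non-missing shared sites: per site the identity-by-state
#' of two dosages is `1 - |d_i - d_j| / 2`.
#'
#' @param gm an [sv_genotypes()] object.
#' @return a `dist` object.
#' @export
allele_sharing_dist <- function(gm) {
  d <- gt_dosage(gm)
  n <- ncol(d)
  m <- matrix(0, n, n, dimnames = list(gm$accessions, gm$accessions))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      if (!any(ok))
        stop("accessions ", gm$accessions[i], " and ", gm$accessions[j],
             " share no non-missing sites")
      m[i, j] <- m[j, i] <- mean(abs(d[ok, i] - d[ok, j]) / 2)
    }
  }
  stats::as.dist(m)
}

#' Neighbour-joining tree with site-resampling bootstrap
#'
#' Saitou-Nei NJ on the allele-sharing distance; bootstrap replicates
#' resample SV sites with replacement and support is the number of
#' replicates containing each internal bipartition (out of
#' `n_bootstrap`, stored in `node.label`).
#'
#' @param gm an [sv_genotypes()] object with at least 3 accessions.
#' @param n_bootstrap bootstrap replicates (0 disables).
#' @param seed RNG seed.
#' @return an `ape::phylo` tree; internal node labels hold bootstrap
#'   counts when bootstrapping was run.
#' @export
nj_tree <- function(gm, n_bootstrap = 100, seed = 1) {
  if (ncol(gm$gt) < 3) stop("need at least 3 accessions")
  tree <- ape::nj(allele_sharing_dist(gm))
  if (n_bootstrap > 0) {
    boots <- with_seed(seed, lapply(seq_len(n_bootstrap), function(b) {
      idx <- sample(nrow(gm$gt), replace = TRUE)
      ape::nj(allele_sharing_dist(sv_genotypes(
        gm$gt[idx, , drop = FALSE],
        gm$sites[idx, , drop = FALSE])))
    }))
    supp <- ape::prop.clades(tree, boots, rooted = FALSE)
    supp[is.na(supp)] <- 0
    tree$node.label <- supp
  }
  tree
}

#' Wild-vs-cultivated allele-frequency-difference selection scan
#'
#' Allele frequencies are computed per group from non-missing alleles;
#' sites whose absolute frequency difference strictly exceeds `threshold`
#' are reported, annotated with genes overlapped by the SV interval or
#' its +/- `flank`.
#'
#' @param gm an [sv_genotypes()] object.
#' @param pops data.frame `accession`, `group` with groups `"wild"` and
#'   `"cultivated"` (additional column names accepted via `group_col`).
#' @param threshold Δf threshold (strict >).
#' @param genes optional gene table for overlap annotation.
#' @param flank overlap flank, bp.
#' @param group_col column of `pops` holding the two-group assignment.
#' @return data.frame of hits: `site_id`, `freq_wild`, `freq_cult`,
#'   `delta_f`, `genes`.
#' @export
freq_diff_scan <- function(gm, pops, threshold = 0.5, genes = NULL,
                           flank = 2000, group_col = "group") {
  grp <- pops[[group_col]][match(gm$accessions, pops$accession)]
  if (anyNA(grp)) stop("every accession needs a population assignment")
  for (g in c("wild", "cultivated"))
    if (!any(grp == g)) stop("group absent: ", g)
  d <- gt_dosage(gm)
  freq_of <- function(rows) {
    apply(d[, rows, drop = FALSE], 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_real_)
      sum(x) / (2 * length(x))
    })
  }
  fw <- freq_of(grp == "wild")
  fc <- freq_of(grp == "cultivated")
  delta <- abs(fw - fc)
  hit <- !is.na(delta) & delta > threshold
  out <- data.frame(site_id = gm$sites$site_id[hit],
                    freq_wild = fw[hit], freq_cult = fc[hit],
                    delta_f = delta[hit], genes = rep("", sum(hit)))
  if (!is.null(genes) && nrow(out) > 0 &&
      all(c("chrom", "pos", "end") %in% names(gm$sites))) {
    st <- gm$sites[hit, , drop = FALSE]
    out$genes <- vapply(seq_len(nrow(st)), function(i) {
      g <- genes[genes$chrom == st$chrom[i], , drop = FALSE]
      ov <- g$gene_id[g$start - flank < st$end[i] &
                        g$end + flank > st$pos[i]]
      paste(ov, collapse = ",")
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Per-site Weir-Cockerham (1984) Fst between two populations
#'
#' Variance-components estimator for diploid individuals with unequal
#' sample sizes (no inbreeding component), the per-site estimator
#' popularized by VCFtools. Sites monomorphic across both populations are
#' undefined (NA), not 0. Windowed values are the ratio of summed
#' numerators to summed denominators.
#'
#' @param gm an [sv_genotypes()] object.
#' @param pops data.frame `accession`, `group` (two groups).
#' @param group_col column of `pops` with the assignment.
#' @param window,step optional window/step in bp over `gm$sites$pos` for
#'   windowed means.
#' @return data.frame `site_id`, `fst`, `a` (numerator), `abc`
#'   (denominator), `n1`, `n2`, `p1`, `p2`; when windows are requested,
#'   the result carries a `windows` attribute.
#' @export
fst_wc <- function(gm, pops, group_col = "group", window = NULL,
                   step = NULL) {
  grp <- pops[[group_col]][match(gm$accessions, pops$accession)]
  if (anyNA(grp)) stop("every accession needs a population assignment")
  gs <- unique(grp)
  if (length(gs) != 2) stop("exactly two populations required")
  d <- gt_dosage(gm)
  res <- t(apply(d, 1, function(x) {
    wc84_site(x[grp == gs[1]], x[grp == gs[2]])
  }))
  out <- data.frame(site_id = gm$sites$site_id, fst = res[, "fst"],
                    a = res[, "a"], abc = res[, "abc"],
                    n1 = res[, "n1"], n2 = res[, "n2"],
                    p1 = res[, "p1"], p2 = res[, "p2"])
  rownames(out) <- NULL
  if (!is.null(window)) {
    step <- step %||% window
    pos <- gm$sites$pos
    wins <- list()
    for (cn in unique(gm$sites$chrom)) {
      onc <- gm$sites$chrom == cn
      if (!any(onc)) next
      maxp <- max(pos[onc])
      starts <- seq(0, maxp, by = step)
      for (ws in starts) {
        idx <- which(onc & pos >= ws & pos < ws + window & !is.na(out$abc))
        idx <- idx[out$abc[idx] > 0]
        if (length(idx) == 0) next
        wins[[length(wins) + 1]] <- data.frame(
          chrom = cn, start = ws, end = ws + window,
          n_sites = length(idx),
          fst = sum(out$a[idx]) / sum(out$abc[idx]))
      }
    }
    attr(out, "windows") <- if (length(wins) > 0) do.call(rbind, wins)
      else data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sites = integer(),
                      fst = numeric())
  }
  out
}

# WC84 variance components for one site, two diploid samples (dosages)
wc84_site <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  empty <- c(fst = NA_real_, a = NA_real_, abc = NA_real_,
             n1 = n1, n2 = n2, p1 = NA_real_, p2 = NA_real_)
  if (n1 < 1 || n2 < 1) return(empty)
  p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
  h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(empty)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  if (pbar == 0 || pbar == 1) {
    return(c(fst = NA_real_, a = NA_real_, abc = NA_real_,
             n1 = n1, n2 = n2, p1 = p1, p2 = p2))
  }
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  abc <- a + b + cc
  fst <- if (abc == 0) NA_real_ else a / abc
  c(fst = fst, a = a, abc = abc, n1 = n1, n2 = n2, p1 = p1, p2 = p2)
}

#' Windowed nucleotide diversity
#'
#' Per window, `pi = sum over sites of 2 p (1-p) n/(n-1)` divided by the
#' window length in bp, with `p` and the allele count `n` computed from
#' non-missing alleles at each site. Empty windows get `pi = 0` with a
#' zero-site flag.
#'
#' @param gm an [sv_genotypes()] object with positions in `gm$sites$pos`.
#' @param window window size, bp.
#' @param step step size, bp (must not exceed `window`).
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `pi`.
#' @export
pi_window <- function(gm, window, step = window) {
  if (step > window) stop("window must be >= step")
  d <- gt_dosage(gm)
  per_site <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    n <- 2 * length(x)
    if (n < 2) return(0)
    p <- sum(x) / n
    2 * p * (1 - p) * n / (n - 1)
  })
  pos <- gm$sites$pos
  rows <- list()
  for (cn in unique(gm$sites$chrom)) {
    onc <- gm$sites$chrom == cn
    maxp <- max(pos[onc])
    for (ws in seq(0, maxp, by = step)) {
      idx <- which(onc & pos >= ws & pos < ws + window)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cn, start = ws, end = ws + window,
        n_sites = length(idx),
        pi = sum(per_site[idx]) / window)
    }
  }
  do.call(rbind, rows)
}
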