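# two differentiated populations with planted sweep sites
fix_pops <- function() fixture("pops", function() {
  with_seed_local(90, {
    n_sites <- 120
    fw <- runif(n_sites, 0.05, 0.95)
    fc <- pmin(pmax(fw + runif(n_sites, -0.15, 0.15), 0), 1)
    sweep <- sample(n_sites, 15)
    fw[sweep] <- runif(15, 0.85, 1)
    fc[sweep] <- runif(15, 0, 0.15)
    spec <- population_spec(c(wild = 40, cultivated = 40),
                            cbind(wild = fw, cultivated = fc),
                            missing_rate = 0.03, seed = 91)
    sim <- simulate_population_genotypes(spec)
    list(gm = sim$gm,
         pops = data.frame(accession = sim$pops$accession,
                           group = sim$pops$population),
         sweep = sort(sweep), fw = fw, fc = fc)
  })
})

test_that("PCA standardization: identical accessions coincide, labels split", {
  fx <- fix_pops()
  p <- pca_genotypes(fx$gm, 4)
  expect_true(all(diff(p$explained) <= 1e-12))
  w <- grepl("^wild", rownames(p$coords))
  expect_true(min(p$coords[w, 1]) > max(p$coords[!w, 1]) ||
                max(p$coords[w, 1]) < min(p$coords[!w, 1]))
  # two byte-identical accessions get identical coordinates
  gt <- fx$gm$gt
  gt[, 2] <- gt[, 1]
  p2 <- pca_genotypes(sv_genotypes(gt, fx$gm$sites), 3)
  expect_equal(p2$coords[1, ], p2$coords[2, ], tolerance = 1e-9)
})

test_that("PCA eigenvalues match a dense eigendecomposition oracle", {
  with_seed_local(95, {
    d <- matrix(sample(0:2, 6 * 12, replace = TRUE), 12, 6)
  })
  gm <- sv_genotypes(d)
  p <- pca_genotypes(gm, 6)
  # oracle: explicit covariance eigendecomposition of the standardized
  # matrix
  mu <- rowMeans(d); pp <- mu / 2
  keep <- pp > 0 & pp < 1
  x <- (d[keep, ] - 2 * pp[keep]) / sqrt(2 * pp[keep] * (1 - pp[keep]))
  ev <- eigen(crossprod(x))$values
  expect_equal(sort(p$sdev^2, decreasing = TRUE),
               sort(ev, decreasing = TRUE)[seq_along(p$sdev)],
               tolerance = 1e-8)
  # accession reordering leaves coordinates invariant up to sign
  perm <- c(3, 1, 2, 6, 5, 4)
  p3 <- pca_genotypes(sv_genotypes(d[, perm]), 2)
  for (k in 1:2) {
    a <- unname(p$coords[perm, k]); b <- unname(p3$coords[, k])
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-6)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-6)))
  }
})

test_that("3-taxon NJ branch lengths solve the pairwise equations", {
  gt <- matrix("0/0", 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  gt[1:10, "B"] <- "1/1"   # dAB contribution
  gt[11:24, "C"] <- "1/1"  # dAC
  gm <- sv_genotypes(gt)
  D <- as.matrix(allele_sharing_dist(gm))
  tr <- nj_tree(gm, n_bootstrap = 0)
  cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cp, D, tolerance = 1e-12)
})

test_that("NJ reconstructs random additive trees exactly", {
  with_seed_local(97, {
    for (rep in 1:5) {
      n <- sample(5:8, 1)
      true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
      true <- ape::unroot(true)
      D <- ape::cophenetic.phylo(true)
      est <- ape::nj(as.dist(D))
      expect_equal(ape::dist.topo(ape::unroot(est), true), 0,
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)],
                   D, tolerance = 1e-8)
    }
  })
})

test_that("a clean population split gets full bootstrap support", {
  fx <- fix_pops()
  # subset for speed: 6 wild + 6 cultivated accessions
  idx <- c(1:6, 41:46)
  gm <- sv_genotypes(fx$gm$gt[, idx], fx$gm$sites)
  tr <- nj_tree(gm, n_bootstrap = 100, seed = 7)
  w <- which(grepl("^wild", tr$tip.label))
  # the wild clade's bipartition must appear in all 100 replicates
  mono <- ape::is.monophyletic(tr, tr$tip.label[w])
  expect_true(mono)
  node <- ape::getMRCA(tr, tr$tip.label[w])
  supp <- tr$node.label[node - length(tr$tip.label)]
  expect_equal(supp, 100)
})

test_that("the frequency-difference scan recovers the planted sweep set", {
  fx <- fix_pops()
  hits <- freq_diff_scan(fx$gm, fx$pops, threshold = 0.5)
  true_delta <- abs(fx$fw - fx$fc)
  # planted sweeps have delta > 0.6, neutral sites < 0.2 (parametric);
  # realized frequencies wobble, so compare against realized truth
  d <- gt_dosage(fx$gm)
  w <- fx$pops$group == "wild"
  realized <- abs(
    apply(d[, w], 1, function(x) mean(x, na.rm = TRUE) / 2) -
      apply(d[, !w], 1, function(x) mean(x, na.rm = TRUE) / 2))
  expect_setequal(hits$site_id, fx$gm$sites$site_id[realized > 0.5])
  expect_true(all(hits$delta_f > 0.5))
  # strictness at the boundary: delta exactly 0.5 is excluded
  gt <- matrix(c(rep("1/1", 5), rep("0/0", 5), rep("0/0", 10)), 1, 20)
  pops <- data.frame(accession = sprintf("acc%03d", 1:20),
                     group = rep(c("wild", "cultivated"), each = 10))
  gmb <- sv_genotypes(gt)
  colnames(gmb$gt) <- pops$accession; gmb$accessions <- pops$accession
  f <- freq_diff_scan(gmb, pops, threshold = 0.5)
  expect_equal(nrow(f), 0)  # delta_f = |0.5 - 0| = 0.5, not > 0.5
})

test_that("WC84 Fst matches an independently coded oracle to 1e-10", {
  # oracle: direct transcription of the variance components for r
  # populations of diploids, coded with explicit loops
  oracle_fst <- function(counts1, counts2) {
    pops <- list(counts1, counts2)  # c(n_homref, n_het, n_homalt)
    r <- 2
    n <- vapply(pops, sum, numeric(1))
    p <- vapply(pops, function(x) (2 * x[3] + x[2]) / (2 * sum(x)),
                numeric(1))
    h <- vapply(pops, function(x) x[2] / sum(x), numeric(1))
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    hbar <- sum(n * h) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
                                  ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) return(NA_real_)
    a / (a + b + cc)
  }
  with_seed_local(99, {
    for (i in 1:1000) {
      n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
      c1 <- as.vector(stats::rmultinom(1, n1, runif(3)))
      c2 <- as.vector(stats::rmultinom(1, n2, runif(3)))
      x1 <- rep(c(0, 1, 2), c1); x2 <- rep(c(0, 1, 2), c2)
      got <- pansv:::wc84_site(x1, x2)[["fst"]]
      want <- oracle_fst(c1, c2)
      mono <- (sum(x1) + sum(x2)) %in% c(0, 2 * (n1 + n2))
      if (mono) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  })
})

test_that("Fst is 1 at fixed differences and near 0 without structure", {
  gt <- matrix(c(rep("1/1", 50), rep("0/0", 50)), 1, 100)
  pops <- data.frame(accession = sprintf("a%03d", 1:100),
                     group = rep(c("wild", "cultivated"), each = 50))
  gm <- sv_genotypes(gt)
  colnames(gm$gt) <- pops$accession; gm$accessions <- pops$accession
  expect_equal(fst_wc(gm, pops)$fst, 1)
  # Hardy-Weinberg draws from one frequency: |Fst| < 0.05 at n = 50/50
  with_seed_local(101, {
    x <- rbinom(100, 2, 0.4)
  })
  gm2 <- sv_genotypes(matrix(x, 1, 100,
                             dimnames = list("s1", pops$accession)))
  expect_lt(abs(fst_wc(gm2, pops)$fst), 0.05)
  # monomorphic site is undefined, not zero
  gm3 <- sv_genotypes(matrix(0, 1, 100,
                             dimnames = list("s1", pops$accession)))
  expect_true(is.na(fst_wc(gm3, pops)$fst))
})

test_that("windowed Fst is the ratio of summed components", {
  fx <- fix_pops()
  f <- fst_wc(fx$gm, fx$pops, window = 20000, step = 20000)
  w <- attr(f, "windows")
  expect_gt(nrow(w), 0)
  i <- which(fx$gm$sites$pos < 20000 & !is.na(f$abc) & f$abc > 0)
  expect_equal(w$fst[1], sum(f$a[i]) / sum(f$abc[i]))
})

test_that("pi follows the closed form and is additive over windows", {
  # single site, p = 0.5 from 5 diploids, window 1000
  gt <- c("0/0", "0/1", "1/1", "0/1", "1/0")
  gm <- sv_genotypes(matrix(gt, 1, 5),
                     sites = data.frame(site_id = "s1", chrom = "chr1",
                                        pos = 500, end = 501))
  pw <- pi_window(gm, 1000, 1000)
  expect_equal(pw$pi[1], (2 * 0.25 * 10 / 9) / 1000)
  # monomorphic window
  gm0 <- sv_genotypes(matrix("0/0", 1, 5),
                      sites = data.frame(site_id = "s1", chrom = "chr1",
                                         pos = 500, end = 501))
  expect_equal(pi_window(gm0, 1000, 1000)$pi[1], 0)
  # additivity: two adjacent windows average (length-weighted) to the
  # combined window
  fx <- fix_pops()
  pw1 <- pi_window(fx$gm, 30000, 30000)
  pw2 <- pi_window(fx$gm, 60000, 60000)
  expect_equal(pw2$pi[1], (pw1$pi[1] * 30000 + pw1$pi[2] * 30000) / 60000)
})
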