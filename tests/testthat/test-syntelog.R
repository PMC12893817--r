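panel2 <- function() fixture("panel2", function()
  simulate_gene_panel(2, n_core = 20, n_disp = 6, n_priv = 6, seed = 2))

test_that("identical genes pair at identity 1 and randomized genes drop out", {
  p <- simulate_gene_panel(2, n_core = 10, n_disp = 0, n_priv = 0,
                           seed = 4, snp_rate = 0)
  a <- p$genomes[[1]]; b <- p$genomes[[2]]
  pr <- score_gene_pairs(a, b)
  expect_setequal(pr$gene_a, a$genes$gene_id)
  self <- pr[pr$gene_a == pr$gene_b, ]
  expect_equal(nrow(self), 10)
  expect_true(all(self$identity == 1))
  # replace one gene's CDS in b by random sequence: no pair at 0.5 identity
  gid <- b$genes$gene_id[1]
  i <- match(gid, b$genes$gene_id)
  ex <- b$genes$exons[[i]]
  chrom <- b$chromosomes[[1]]
  for (r in seq_len(nrow(ex))) {
    chrom <- pansv:::splice0(chrom, ex[r, 1], ex[r, 2],
                             with_seed_local(9, random_dna(ex[r, 2] -
                                                             ex[r, 1])))
  }
  b2 <- annotated_genome("g2r", c(chr1 = chrom), b$genes)
  pr2 <- score_gene_pairs(a, b2)
  expect_false(gid %in% pr2$gene_b)
})

test_that("a duplicated gene keeps both hits under top-N", {
  p <- simulate_gene_panel(2, n_core = 8, n_disp = 0, n_priv = 0,
                           seed = 6, snp_rate = 0)
  a <- p$genomes[[1]]; b <- p$genomes[[2]]
  # append a tandem copy of b's first gene at the chromosome end
  i <- 1
  ex <- b$genes$exons[[i]]
  span <- c(b$genes$start[i], b$genes$end[i])
  copy_seq <- pansv:::subseq0(b$chromosomes[[1]], span[1], span[2])
  off <- nchar(b$chromosomes[[1]]) + 200 - span[1]
  chrom <- paste0(b$chromosomes[[1]], with_seed_local(10, random_dna(200)),
                  copy_seq)
  genes <- rbind(b$genes, data.frame(
    gene_id = "dup_copy", chrom = "chr1", strand = b$genes$strand[i],
    start = span[1] + off, end = span[2] + off,
    exons = I(list(ex + off))))
  b2 <- annotated_genome("g2d", c(chr1 = chrom), genes)
  pr <- score_gene_pairs(a, b2)
  hits <- pr[pr$gene_a == b$genes$gene_id[1], ]
  expect_setequal(hits$gene_b, c(b$genes$gene_id[1], "dup_copy"))
})

test_that("synteny chaining keeps collinear pairs and drops strays", {
  p <- panel2()
  a <- p$genomes[[1]]; b <- p$genomes[[2]]
  pr <- score_gene_pairs(a, b)
  syn <- synteny_chain_genes(pr, a, b)
  # shared panel genes are collinear by construction: all 1:1 pairs kept
  shared <- intersect(a$genes$gene_id, b$genes$gene_id)
  kept11 <- syn[syn$gene_a == syn$gene_b, ]
  expect_setequal(kept11$gene_a, shared)
  # an artificial stray pair (wrong position) is dropped
  stray <- data.frame(genome_a = a$genome_id,
                      gene_a = a$genes$gene_id[1],
                      genome_b = b$genome_id,
                      gene_b = b$genes$gene_id[nrow(b$genes)],
                      identity = 1, score = 1e6)
  syn2 <- synteny_chain_genes(rbind(pr, stray), a, b)
  expect_false(any(syn2$gene_a == stray$gene_a &
                     syn2$gene_b == stray$gene_b))
  # min_pairs floor: 4 collinear pairs cannot form a 5-pair chain
  few <- pr[pr$gene_a == pr$gene_b, ][1:4, ]
  expect_equal(nrow(synteny_chain_genes(few, a, b, min_pairs = 5)), 0)
  expect_equal(nrow(synteny_chain_genes(few, a, b, min_pairs = 4)), 4)
})

test_that("longest-collinear-subsequence matches brute force on small sets", {
  # 10 collinear pairs + 1 random cross pair, exhaustive check
  p <- simulate_gene_panel(2, n_core = 10, n_disp = 0, n_priv = 0,
                           seed = 12, snp_rate = 0)
  a <- p$genomes[[1]]; b <- p$genomes[[2]]
  pr <- score_gene_pairs(a, b)
  pr <- pr[pr$gene_a == pr$gene_b, ]
  cross <- data.frame(genome_a = a$genome_id, gene_a = a$genes$gene_id[2],
                      genome_b = b$genome_id,
                      gene_b = b$genes$gene_id[8],
                      identity = 0.9, score = 100)
  all_pairs <- rbind(pr, cross)
  syn <- synteny_chain_genes(all_pairs, a, b)
  # brute force: largest subset collinear with rank gaps <= 10
  ra <- pansv:::gene_ranks(a); rb <- pansv:::gene_ranks(b)
  ia <- ra$rank[match(all_pairs$gene_a, ra$gene_id)]
  ib <- rb$rank[match(all_pairs$gene_b, rb$gene_id)]
  n <- nrow(all_pairs)
  best <- integer()
  for (k in n:1) {
    for (ss in utils::combn(n, k, simplify = FALSE)) {
      o <- ss[order(ia[ss])]
      d_a <- diff(ia[o]); d_b <- diff(ib[o])
      if (all(d_a >= 1 & d_a <= 10) &&
          (all(d_b >= 1 & d_b <= 10) || all(d_b <= -1 & d_b >= -10))) {
        best <- o; break
      }
    }
    if (length(best) > 0) break
  }
  expect_equal(sort(paste(syn$gene_a, syn$gene_b)),
               sort(paste(all_pairs$gene_a, all_pairs$gene_b)[best]))
})

test_that("merging is transitive and single-genome input gives singletons", {
  m1 <- merge_syntelogs(list(panel2()$genomes[[1]]))
  expect_equal(nrow(m1$sgs), nrow(panel2()$genomes[[1]]$genes))
  expect_equal(length(unique(m1$sgs$sg_id)), nrow(m1$sgs))

  # A-B and B-C pairs but no A-C pair still produce one SG {A,B,C}:
  # chain through an artificial pair function
  gnm <- function(id) annotated_genome(id, c(chr1 = strrep("A", 1000)),
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+", start = 10,
               end = 13, exons = I(list(matrix(c(10, 13), 1)))))
  gA <- gnm("A"); gB <- gnm("B"); gC <- gnm("C")
  fake_pairs <- function(gn, gm) {
    link <- (gn$genome_id == "B" && gm$genome_id == "A") ||
      (gn$genome_id == "C" && gm$genome_id == "B")
    if (!link) return(pansv:::empty_pairs())
    data.frame(genome_a = gn$genome_id, gene_a = "g1",
               genome_b = gm$genome_id, gene_b = "g1",
               identity = 1, score = 10)
  }
  m <- merge_syntelogs(list(gA, gB, gC), pair_fun = fake_pairs)
  expect_equal(length(unique(m$sgs$sg_id)), 1)
  expect_equal(nrow(m$sgs), 3)
})

test_that("SG classification and PAV matrix follow the occupancy rule", {
  sgs <- data.frame(
    sg_id = c("SG1", "SG1", "SG1", "SG2", "SG3", "SG3"),
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    gene_id = paste0("x", 1:6))
  cl <- classify_sgs(sgs, n_genomes = 3)
  got <- setNames(cl$classes$class, cl$classes$sg_id)
  expect_equal(got[["SG1"]], "core")
  expect_equal(got[["SG2"]], "private")
  expect_equal(got[["SG3"]], "dispensable")
  expect_equal(sum(table(cl$classes$class)), 3)
  expect_true(all(rowSums(cl$pav) >= 1))
})

test_that("planted core/dispensable/private classes are recovered exactly", {
  p <- fixture("panel3", function()
    simulate_gene_panel(3, n_core = 25, n_disp = 10, n_priv = 6, seed = 8))
  pg <- build_syntelog_pangenome(p$genomes)
  # partition: every gene in exactly one SG
  total_genes <- sum(vapply(p$genomes, function(g) nrow(g$genes),
                            integer(1)))
  expect_equal(nrow(pg$sgs), total_genes)
  expect_equal(pg$counts$core + pg$counts$dispensable + pg$counts$private,
               pg$counts$total)
  # each SG is one template; its class matches the planted class
  sg_map <- split(pg$sgs$gene_id, pg$sgs$sg_id)
  expect_true(all(vapply(sg_map, function(g)
    length(unique(g)) == 1, logical(1))))
  truth_class <- setNames(p$truth$class, p$truth$gene_id)
  got <- setNames(pg$classes$class, pg$classes$sg_id)
  expect_true(all(vapply(names(sg_map), function(sg)
    truth_class[[unique(sg_map[[sg]])]] == got[[sg]], logical(1))))
})

test_that("SG composition is invariant to genome insertion order", {
  p <- fixture("panel3b", function()
    simulate_gene_panel(3, n_core = 15, n_disp = 5, n_priv = 3, seed = 21))
  pg1 <- build_syntelog_pangenome(p$genomes)
  pg2 <- build_syntelog_pangenome(p$genomes[c(2, 3, 1)])
  part <- function(pg) {
    s <- split(paste(pg$sgs$genome_id, pg$sgs$gene_id), pg$sgs$sg_id)
    sort(vapply(s, function(x) paste(sort(x), collapse = "|"),
                character(1)))
  }
  expect_equal(unname(part(pg1)), unname(part(pg2)))
})

test_that("accumulation curves match exhaustive enumeration", {
  pav <- matrix(c(1, 1, 1,
                  1, 1, 0,
                  0, 1, 1,
                  1, 0, 0,
                  0, 0, 1), 5, 3, byrow = TRUE,
                dimnames = list(paste0("SG", 1:5), paste0("g", 1:3)))
  # exact oracle: average over all subsets of each size
  oracle <- function(g) {
    subs <- utils::combn(3, g, simplify = FALSE)
    pan <- mean(vapply(subs, function(s)
      sum(rowSums(pav[, s, drop = FALSE]) >= 1), numeric(1)))
    core <- mean(vapply(subs, function(s)
      sum(rowSums(pav[, s, drop = FALSE]) == g), numeric(1)))
    c(pan = pan, core = core)
  }
  acc <- accumulation_curves(pav, n_perm = 200, seed = 3)
  for (g in 1:3) {
    ex <- oracle(g)
    got_pan <- mean(acc$pan_count[acc$sample_size == g])
    got_core <- mean(acc$core_count[acc$sample_size == g])
    if (g == 3) {
      expect_equal(got_pan, ex[["pan"]])
      expect_equal(got_core, ex[["core"]])
    } else {
      expect_lt(abs(got_pan - ex[["pan"]]), 0.35)
      expect_lt(abs(got_core - ex[["core"]]), 0.35)
    }
  }
  # trivial: everything everywhere
  pav1 <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4),
                                          paste0("g", 1:3)))
  acc1 <- accumulation_curves(pav1, n_perm = 5, seed = 1)
  expect_true(all(acc1$pan_count == 4) && all(acc1$core_count == 4))
  # monotone means on generator output
  p <- fixture("panel3", function()
    simulate_gene_panel(3, n_core = 25, n_disp = 10, n_priv = 6, seed = 8))
  pg <- build_syntelog_pangenome(p$genomes)
  acc2 <- accumulation_curves(pg$pav, n_perm = 50, seed = 5)
  mpan <- tapply(acc2$pan_count, acc2$sample_size, mean)
  mcore <- tapply(acc2$core_count, acc2$sample_size, mean)
  expect_true(all(diff(mpan) >= 0))
  expect_true(all(diff(mcore) <= 0))
  # determinism per seed
  expect_identical(acc2, accumulation_curves(pg$pav, n_perm = 50, seed = 5))
})
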