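#' Score homologous gene pairs between two annotated genomes
#'
#' Translated-CDS local alignment (Smith-Waterman, BLOSUM62): a pair is
#' emitted when the best local alignment reaches `min_identity` and covers
#' at least `min_cov` of the shorter protein. A fast shared-k-mer
#' prescreen shortlists candidate pairs before alignment; per gene the top
#' `top_n` hits are kept. Genes whose CDS length is not divisible by three
#' are skipped (a warning reports the count).
#'
#' @param a,b [annotated_genome()] objects.
#' @param min_identity minimum alignment identity (fraction).
#' @param min_cov minimum coverage of the shorter protein (fraction).
#' @param top_n hits kept per gene.
#' @param prescreen_k nucleotide k-mer size of the candidate prescreen.
#' @param prescreen_min shared k-mers needed to become a candidate.
#' @return data.frame: `genome_a`, `gene_a`, `genome_b`, `gene_b`,
#'   `identity`, `score`.
#' @export
score_gene_pairs <- function(a, b, min_identity = 0.5, min_cov = 0.5,
                             top_n = 5, prescreen_k = 12,
                             prescreen_min = 3) {
  prot_a <- translated_cds(a)
  prot_b <- translated_cds(b)
  if (length(prot_a) == 0 || length(prot_b) == 0) return(empty_pairs())
  cds_a <- cds_sequences(a)[names(prot_a)]
  cds_b <- cds_sequences(b)[names(prot_b)]
  # candidate shortlist by shared nucleotide k-mers (vectorized join)
  tab_of <- function(cds) {
    km <- lapply(cds, function(s) unique(seq_kmers(s, prescreen_k)))
    data.frame(km = unlist(km, use.names = FALSE),
               gene = rep(seq_along(km), lengths(km)))
  }
  ka <- tab_of(cds_a); kb <- tab_of(cds_b)
  shared <- merge(ka, kb, by = "km")
  if (nrow(shared) == 0) return(empty_pairs())
  cnt <- table(paste(shared$gene.x, shared$gene.y))
  cand <- do.call(rbind, strsplit(names(cnt)[cnt >= prescreen_min], " "))
  if (is.null(cand)) return(empty_pairs())
  cand <- data.frame(i = as.integer(cand[, 1]), j = as.integer(cand[, 2]))
  aa <- Biostrings::AAStringSet(prot_a)
  bb <- Biostrings::AAStringSet(prot_b)
  aln <- Biostrings::pairwiseAlignment(
    aa[cand$i], bb[cand$j], type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  cov <- Biostrings::nchar(aln) /
    pmin(nchar(prot_a)[cand$i], nchar(prot_b)[cand$j])
  keep <- ident >= min_identity & cov >= min_cov
  if (!any(keep)) return(empty_pairs())
  out <- data.frame(
    genome_a = a$genome_id, gene_a = names(prot_a)[cand$i[keep]],
    genome_b = b$genome_id, gene_b = names(prot_b)[cand$j[keep]],
    identity = ident[keep], score = Biostrings::score(aln)[keep])
  # keep top-N hits per gene on either side
  keep_top <- function(df, key) {
    unlist(lapply(split(seq_len(nrow(df)), df[[key]]), function(idx) {
      idx[order(-df$score[idx])][seq_len(min(top_n, length(idx)))]
    }))
  }
  out <- out[intersect(keep_top(out, "gene_a"), keep_top(out, "gene_b")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(genome_a = character(), gene_a = character(),
             genome_b = character(), gene_b = character(),
             identity = numeric(), score = numeric())
}

# proteins for all genes with in-frame CDS; warns with a skip count
translated_cds <- function(genome) {
  cds <- cds_sequences(genome)
  if (length(cds) == 0) return(character())
  ok <- nchar(cds) %% 3 == 0
  if (any(!ok))
    warning(sum(!ok), " gene(s) with CDS length not divisible by 3 ",
            "skipped in ", genome$genome_id)
  cds <- cds[ok]
  prots <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), if.fuzzy.codon = "X"))
  prots <- sub("\\*$", "", prots)
  names(prots) <- names(cds)
  prots[nchar(prots) > 0]
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1), k:n)
}

#' Filter homolog pairs down to syntenic (collinear) pairs
#'
#' Dynamic programming over the gene-rank dot plot per chromosome pair:
#' retained pairs lie on collinear chains (either orientation) with at
#' least `min_pairs` members and inter-pair rank gaps of at most
#' `max_gene_gap` on both genomes. Chains are extracted best-first until
#' none reaches `min_pairs`.
#'
#' @param pairs data.frame from [score_gene_pairs()].
#' @param a,b the two [annotated_genome()] objects (for gene order).
#' @param min_pairs minimum pairs per chain.
#' @param max_gene_gap maximum rank gap between consecutive chain members.
#' @return the syntenic subset of `pairs`.
#' @export
synteny_chain_genes <- function(pairs, a, b, min_pairs = 5,
                                max_gene_gap = 10) {
  if (nrow(pairs) == 0) return(pairs)
  ra <- gene_ranks(a); rb <- gene_ranks(b)
  ia <- match(pairs$gene_a, ra$gene_id)
  ib <- match(pairs$gene_b, rb$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair gene missing from genome tables")
  df <- data.frame(idx = seq_len(nrow(pairs)),
                   chrom_a = ra$chrom[ia], rank_a = ra$rank[ia],
                   chrom_b = rb$chrom[ib], rank_b = rb$rank[ib],
                   score = pairs$score)
  kept <- integer()
  for (stratum in split(df, paste(df$chrom_a, df$chrom_b))) {
    for (dir in c(1, -1)) {
      s <- stratum
      s$rb2 <- dir * s$rank_b
      s <- s[order(s$rank_a, s$rb2), ]
      avail <- rep(TRUE, nrow(s))
      repeat {
        idx <- which(avail)
        if (length(idx) < min_pairs) break
        n <- length(idx)
        best <- rep(1L, n); pred <- rep(NA_integer_, n)
        for (i in seq_len(n)) {
          for (j in seq_len(i - 1L)) {
            dga <- s$rank_a[idx[i]] - s$rank_a[idx[j]]
            dgb <- s$rb2[idx[i]] - s$rb2[idx[j]]
            if (dga >= 1 && dgb >= 1 && dga <= max_gene_gap &&
                dgb <= max_gene_gap && best[j] + 1L > best[i]) {
              best[i] <- best[j] + 1L; pred[i] <- j
            }
          }
        }
        top <- which.max(best)
        if (best[top] < min_pairs) break
        chain <- integer()
        i <- top
        while (!is.na(i)) { chain <- c(chain, i); i <- pred[i] }
        kept <- c(kept, s$idx[idx[chain]])
        avail[idx[chain]] <- FALSE
      }
    }
  }
  out <- pairs[sort(unique(kept)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge genomes into syntelog groups (SGs)
#'
#' Iterative merging: every gene of the framework (first) genome seeds an
#' SG; each later genome's genes join the SG of their best syntenically
#' paired gene among all previously merged genes (ties broken by highest
#' alignment score, then lowest SG id), and unpaired genes seed new SGs.
#' Every gene belongs to exactly one SG.
#'
#' @param genomes list of [annotated_genome()] objects; the first is the
#'   framework.
#' @param pair_fun function(genome_new, genome_merged) returning syntenic
#'   pairs (columns as [score_gene_pairs()]); defaults to
#'   [score_gene_pairs()] followed by [synteny_chain_genes()] with the
#'   supplied parameters.
#' @param ... passed to the default pair function.
#' @return list with `sgs` (data.frame `sg_id`, `genome_id`, `gene_id`)
#'   and `membership` (list sg_id -> genome -> gene ids).
#' @export
merge_syntelogs <- function(genomes, pair_fun = NULL, ...) {
  stopifnot(length(genomes) >= 1)
  pair_fun <- pair_fun %||% function(gn, gm) {
    p <- score_gene_pairs(gn, gm, ...)
    synteny_chain_genes(p, gn, gm)
  }
  sg_of <- list()  # genome -> named vector gene_id -> sg_id
  fw <- genomes[[1]]
  n_sg <- nrow(fw$genes)
  sg_of[[fw$genome_id]] <- setNames(seq_len(n_sg), fw$genes$gene_id)
  for (gi in seq_along(genomes)[-1]) {
    gn <- genomes[[gi]]
    # best syntenic partner per new gene across all merged genomes
    cand <- list()  # gene -> (sg, score)
    for (gj in seq_len(gi - 1)) {
      gm <- genomes[[gj]]
      p <- pair_fun(gn, gm)
      for (r in seq_len(nrow(p))) {
        gene <- p$gene_a[r]
        sg <- unname(sg_of[[gm$genome_id]][p$gene_b[r]])
        if (is.na(sg)) next
        prev <- cand[[gene]]
        better <- is.null(prev) || p$score[r] > prev$score ||
          (p$score[r] == prev$score && sg < prev$sg)
        if (better) cand[[gene]] <- list(sg = sg, score = p$score[r])
      }
    }
    assigned <- setNames(integer(nrow(gn$genes)), gn$genes$gene_id)
    for (gene in gn$genes$gene_id) {
      if (!is.null(cand[[gene]])) {
        assigned[gene] <- cand[[gene]]$sg
      } else {
        n_sg <- n_sg + 1L
        assigned[gene] <- n_sg
      }
    }
    sg_of[[gn$genome_id]] <- assigned
  }
  sgs <- do.call(rbind, lapply(names(sg_of), function(g)
    data.frame(sg_id = sprintf("SG%05d", unname(sg_of[[g]])),
               genome_id = g, gene_id = names(sg_of[[g]]))))
  sgs <- sgs[order(sgs$sg_id, sgs$genome_id, sgs$gene_id), ]
  rownames(sgs) <- NULL
  membership <- lapply(split(sgs, sgs$sg_id), function(df)
    lapply(split(df$gene_id, df$genome_id), identity))
  list(sgs = sgs, membership = membership)
}

#' Classify SGs into core, dispensable and private, with a PAV matrix
#'
#' An SG present in all `n_genomes` genomes is core; present in exactly
#' one, private; anything in between, dispensable.
#'
#' @param sgs data.frame (`sg_id`, `genome_id`, `gene_id`) from
#'   [merge_syntelogs()].
#' @param n_genomes total number of genomes in the pangenome.
#' @return list with `classes` (data.frame `sg_id`, `n_genomes`, `class`)
#'   and `pav` (binary matrix SG x genome).
#' @export
classify_sgs <- function(sgs, n_genomes) {
  stopifnot(n_genomes >= 2)
  if (nrow(sgs) == 0) stop("no SGs to classify")
  pav <- table(sgs$sg_id, sgs$genome_id) > 0
  pav <- matrix(as.integer(pav), nrow(pav), ncol(pav),
                dimnames = dimnames(pav))
  n <- rowSums(pav)
  if (any(n == 0)) stop("SG with zero members: invariant violation")
  cls <- ifelse(n == n_genomes, "core",
                ifelse(n == 1, "private", "dispensable"))
  list(classes = data.frame(sg_id = rownames(pav), n_genomes = as.vector(n),
                            class = as.vector(cls)),
       pav = pav)
}

#' Pan/core accumulation curves by random genome sampling
#'
#' For each sample size g in 1..n_genomes and each of `n_perm` replicates,
#' g genomes are drawn without replacement; the pan count is the number of
#' SGs present in at least one sampled genome and the core count the
#' number present in all of them.
#'
#' @param pav binary SG x genome matrix (from [classify_sgs()]).
#' @param n_perm replicates per sample size.
#' @param seed RNG seed.
#' @return data.frame: `sample_size`, `replicate`, `pan_count`,
#'   `core_count`.
#' @export
accumulation_curves <- function(pav, n_perm = 100, seed = 1) {
  stopifnot(n_perm >= 1)
  n_g <- ncol(pav)
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(n_g)) {
      for (r in seq_len(n_perm)) {
        pick <- sample(n_g, g)
        sub <- pav[, pick, drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          sample_size = g, replicate = r,
          pan_count = sum(rowSums(sub) >= 1),
          core_count = sum(rowSums(sub) == g))
      }
    }
    do.call(rbind, rows)
  })
}

#' Build the full syntelog pangenome from a genome list
#'
#' Convenience wrapper: merge, classify and summarize.
#'
#' @param genomes list of [annotated_genome()]; first = framework.
#' @param ... passed to [score_gene_pairs()] via [merge_syntelogs()].
#' @return list with `sgs`, `classes`, `pav`, `counts` (core,
#'   dispensable, private, total).
#' @export
build_syntelog_pangenome <- function(genomes, ...) {
  m <- merge_syntelogs(genomes, ...)
  cl <- classify_sgs(m$sgs, n_genomes = length(genomes))
  counts <- table(factor(cl$classes$class,
                         levels = c("core", "dispensable", "private")))
  list(sgs = m$sgs, classes = cl$classes, pav = cl$pav,
       counts = c(as.list(counts), total = nrow(cl$classes)))
}
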