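#' Genotype matrix container
#'
#' Holds diploid genotype calls for SV sites across accessions. The
#' canonical store is the GT string matrix (`"0/0"`, `"0/1"`, `"1/1"`,
#' `"./."`, allele-indexed such as `"1/2"` at multiallelic sites); a
#' numeric dosage matrix (count of allele 1, NA for missing or
#' higher-allele genotypes) is derived on construction.
#'
#' @param x either a GT character matrix or a dosage matrix (0/1/2/NA),
#'   sites x accessions.
#' @param sites data.frame of per-site metadata with at least `site_id`;
#'   `chrom`, `pos`, `end`, `type` are used by positional annotation.
#' @return An `sv_genotypes` object.
#' @export
sv_genotypes <- function(x, sites = NULL) {
  if (is.numeric(x)) {
    gt <- matrix(ifelse(is.na(x), "./.",
                        c("0/0", "0/1", "1/1")[x + 1]),
                 nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    gt <- x
  }
  sites <- sites %||% data.frame(site_id = rownames(gt) %||%
                                   sprintf("site%04d", seq_len(nrow(gt))))
  stopifnot(nrow(sites) == nrow(gt))
  if (is.null(rownames(gt))) rownames(gt) <- sites$site_id
  structure(list(gt = gt, sites = sites,
                 accessions = colnames(gt) %||%
                   sprintf("acc%03d", seq_len(ncol(gt)))),
            class = "sv_genotypes")
}

#' @export
print.sv_genotypes <- function(x, ...) {
  cat(sprintf("<sv_genotypes> %d site(s) x %d accession(s), %.1f%% missing\n",
              nrow(x$gt), ncol(x$gt), 100 * mean(x$gt == "./.")))
  invisible(x)
}

#' Dosage matrix of an sv_genotypes object
#'
#' @param gm an [sv_genotypes()] object.
#' @return numeric matrix of allele-1 dosages (NA for missing genotypes
#'   and genotypes involving alleles above 1).
#' @export
gt_dosage <- function(gm) {
  d <- matrix(NA_real_, nrow(gm$gt), ncol(gm$gt), dimnames = dimnames(gm$gt))
  d[gm$gt == "0/0"] <- 0
  d[gm$gt %in% c("0/1", "1/0")] <- 1
  d[gm$gt == "1/1"] <- 2
  d
}

# per-site allele frequency table from GT strings (non-missing alleles)
site_allele_freqs <- function(gt_row) {
  al <- unlist(strsplit(gt_row[gt_row != "./."], "/", fixed = TRUE))
  if (length(al) == 0) return(numeric())
  prop.table(table(al))
}

#' Build the allele-distinctive k-mer index of a pangenome graph
#'
#' For every variant site, each allele (backbone and alternatives) is
#' flanked by k-1 bp of backbone context on both sides and decomposed into
#' k-mers; k-mers shared between alleles of a site are dropped, leaving
#' the allele-distinctive set (including breakpoint junction k-mers).
#'
#' @param graph a `pan_graph` from [build_graph()].
#' @param k k-mer size.
#' @return list with `kmers`, `group` (parallel vectors), and `meta`
#'   (data.frame `group`, `site`, `allele` - 0 is the backbone allele -
#'   and `n_kmers`; sites with an allele lacking distinctive k-mers are
#'   flagged `ungenotypeable`).
#' @export
allele_kmer_index <- function(graph, k = 31) {
  backbone_seq <- lapply(
    setNames(nm = names(graph$paths[[graph$backbone]])),
    function(cn) path_sequence(graph, graph$backbone, cn))
  kmers <- character(); group <- integer()
  meta <- data.frame(group = integer(), site = integer(),
                     allele = integer(), n_kmers = integer(),
                     ungenotypeable = logical())
  gid <- 0L
  for (si in seq_along(graph$sites)) {
    s <- graph$sites[[si]]
    cs <- backbone_seq[[s$chrom]]
    lf <- subseq0(cs, max(0, s$ref_start - (k - 1)), s$ref_start)
    rf <- subseq0(cs, s$ref_end, min(nchar(cs), s$ref_end + (k - 1)))
    alleles <- c(s$ref_seq, s$alt_seqs)
    sets <- lapply(alleles, function(a) unique(seq_kmers(
      paste0(lf, a, rf), k)))
    distinct <- lapply(seq_along(sets), function(i) {
      others <- unique(unlist(sets[-i]))
      setdiff(sets[[i]], others)
    })
    bad <- any(vapply(distinct, length, integer(1)) == 0)
    for (ai in seq_along(alleles)) {
      gid <- gid + 1L
      km <- distinct[[ai]]
      kmers <- c(kmers, km)
      group <- c(group, rep(gid, length(km)))
      meta <- rbind(meta, data.frame(group = gid, site = si,
                                     allele = ai - 1L,
                                     n_kmers = length(km),
                                     ungenotypeable = bad))
    }
  }
  list(kmers = kmers, group = group, meta = meta,
       n_sites = length(graph$sites), k = k)
}

#' Genotype one accession's reads against graph bubbles
#'
#' Counts reads supporting each allele through allele-distinctive k-mers
#' and converts normalized allele depths into diploid calls: alternative
#' fraction at most 0.2 is called 0/0, at least 0.8 is 1/1, anything in
#' between 0/1; sites with total supporting depth below `min_depth` (or
#' an allele with no distinctive k-mer) are missing (`./.`). At
#' multiallelic sites the best-supported pair of alleles is called.
#'
#' @param reads data.frame (`read_id`, `seq`) as from [simulate_reads()].
#' @param graph a `pan_graph`.
#' @param k k-mer size (must match `index` when supplied).
#' @param min_depth minimum mean per-k-mer depth across the two called
#'   alleles.
#' @param index optional precomputed [allele_kmer_index()].
#' @return character vector of GT strings, one per graph site.
#' @export
genotype_accession <- function(reads, graph, k = 31, min_depth = 4,
                               index = NULL) {
  index <- index %||% allele_kmer_index(graph, k)
  counts <- .count_kmer_hits_cpp(reads$seq, index$kmers, index$group,
                                 max(index$meta$group), index$k)
  meta <- index$meta
  depth <- ifelse(meta$n_kmers > 0, counts[meta$group] / meta$n_kmers,
                  NA_real_)
  out <- character(index$n_sites)
  for (si in seq_len(index$n_sites)) {
    rows <- which(meta$site == si)
    if (length(rows) == 0 || any(meta$ungenotypeable[rows])) {
      out[si] <- "./."
      next
    }
    d <- depth[rows]
    alleles <- meta$allele[rows]
    ord <- order(-d)
    top <- ord[1]; second <- if (length(ord) > 1) ord[2] else NA
    d1 <- d[top]; d2 <- if (!is.na(second)) d[second] else 0
    if (d1 + d2 < min_depth) {
      out[si] <- "./."
      next
    }
    frac2 <- d2 / (d1 + d2)
    a1 <- alleles[top]; a2 <- alleles[second]
    gt <- if (frac2 <= 0.2) c(a1, a1)
          else if (frac2 >= 0.8) c(a2, a2)
          else c(a1, a2)
    out[si] <- paste(sort(gt), collapse = "/")
  }
  out
}

#' Genotype a panel of accessions against graph bubbles
#'
#' @param reads_list named list of read data.frames, one per accession.
#' @param graph a `pan_graph`.
#' @param k k-mer size.
#' @param min_depth see [genotype_accession()].
#' @return an [sv_genotypes()] object (sites = graph sites).
#' @export
genotype_panel <- function(reads_list, graph, k = 31, min_depth = 4) {
  index <- allele_kmer_index(graph, k)
  gt <- vapply(reads_list, function(rd)
    genotype_accession(rd, graph, k = k, min_depth = min_depth,
                       index = index),
    character(index$n_sites))
  sites <- do.call(rbind, lapply(seq_along(graph$sites), function(i) {
    s <- graph$sites[[i]]
    data.frame(site_id = sprintf("bub%05d", i), chrom = s$chrom,
               pos = s$ref_start, end = s$ref_end,
               type = if (length(s$alt_seqs) > 1) "Multi" else {
                 if (nchar(s$ref_seq) == 0) "Ins"
                 else if (nchar(s$alt_seqs[1]) == 0) "Del" else "Div"
               })
  }))
  rownames(gt) <- sites$site_id
  sv_genotypes(gt, sites)
}

#' Filter SV sites on missingness and minor allele frequency
#'
#' Sites are dropped first when their missing fraction exceeds
#' `max_missing`, then when their minor allele frequency (computed over
#' non-missing alleles; the smallest allele frequency at multiallelic
#' sites) falls below `min_maf`. The report accounts for both steps
#' sequentially.
#'
#' @param gm an [sv_genotypes()] object.
#' @param max_missing maximum tolerated missing fraction per site.
#' @param min_maf minimum minor allele frequency.
#' @return list with `gm` (filtered matrix) and `report` (n_input,
#'   n_fail_missing, n_fail_maf, n_pass).
#' @export
filter_sites <- function(gm, max_missing = 0.3, min_maf = 0.01) {
  stopifnot(inherits(gm, "sv_genotypes"))
  n_input <- nrow(gm$gt)
  if (n_input == 0) stop("empty genotype matrix")
  miss_frac <- rowMeans(gm$gt == "./.")
  fail_miss <- miss_frac > max_missing
  maf <- apply(gm$gt, 1, function(row) {
    f <- site_allele_freqs(row)
    if (length(f) == 0) return(NA_real_)
    if (length(f) == 1) return(0)
    min(f)
  })
  fail_maf <- !fail_miss & (is.na(maf) | maf < min_maf)
  pass <- !fail_miss & !fail_maf
  if (!any(pass)) warning("all sites removed by filtering")
  out <- sv_genotypes(gm$gt[pass, , drop = FALSE],
                      gm$sites[pass, , drop = FALSE])
  list(gm = out,
       report = list(n_input = n_input,
                     n_fail_missing = sum(fail_miss),
                     n_fail_maf = sum(fail_maf),
                     n_pass = sum(pass)))
}

#' Classify SV positions relative to gene models
#'
#' Precedence coding > intron > regulatory > intergenic: an SV overlapping
#' any exon is `coding`; overlapping a gene body without touching exons,
#' `intron`; within `flank` bp of a gene, `regulatory` (with a
#' strand-aware upstream/downstream detail); otherwise `intergenic`.
#'
#' @param svs data.frame with `chrom`, `pos`, `end` (0-based half-open).
#' @param genes gene table of an [annotated_genome()] (or lifted
#'   equivalent).
#' @param flank regulatory flank width, bp.
#' @return `svs` with added columns `location` and `detail`.
#' @export
annotate_sv_position <- function(svs, genes, flank = 2000) {
  location <- character(nrow(svs)); detail <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    s <- svs$pos[i]; e <- max(svs$end[i], svs$pos[i] + 1)
    g <- genes[genes$chrom == svs$chrom[i], , drop = FALSE]
    loc <- "intergenic"; det <- ""
    if (nrow(g) > 0) {
      body <- which(g$start < e & g$end > s)
      in_exon <- any(vapply(body, function(bi) {
        ex <- g$exons[[bi]]
        any(ex[, 1] < e & ex[, 2] > s)
      }, logical(1)))
      if (in_exon) {
        loc <- "coding"
      } else if (length(body) > 0) {
        loc <- "intron"
        det <- g$gene_id[body[1]]
      } else {
        near <- which(g$start - flank < e & g$end + flank > s)
        if (length(near) > 0) {
          loc <- "regulatory"
          bi <- near[1]
          before <- e <= g$start[bi]
          det <- if (g$strand[bi] == "+") {
            if (before) "upstream" else "downstream"
          } else {
            if (before) "downstream" else "upstream"
          }
          det <- paste0(g$gene_id[bi], ":", det)
        }
      }
    }
    location[i] <- loc; detail[i] <- det
  }
  cbind(svs, location = location, detail = detail)
}
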