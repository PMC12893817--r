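#' Simulate an ancestral annotated genome
#'
#' Generates random chromosome sequences and places multi-exon
#' protein-coding genes at non-overlapping loci. Every gene has at least
#' two exons (so introns exist), an ATG start, a stop codon and a CDS
#' length divisible by three. The result is deterministic per seed.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_len length of each chromosome in bp (>= 10 kb).
#' @param n_genes total number of genes to place.
#' @param seed RNG seed.
#' @param gc GC content of the background sequence.
#' @param genome_id genome name.
#' @return An [annotated_genome()].
#' @export
simulate_ancestor <- function(n_chrom, chrom_len, n_genes, seed,
                              gc = 0.5, genome_id = "ancestor") {
  stopifnot(n_chrom >= 1, chrom_len >= 10000, n_genes >= 0)
  with_seed(seed, {
    chroms <- setNames(
      vapply(seq_len(n_chrom), function(i) random_dna(chrom_len, gc),
             character(1)),
      paste0("chr", seq_len(n_chrom)))
    genes <- empty_genes()
    if (n_genes > 0) {
      tpl <- lapply(seq_len(n_genes), function(i)
        make_gene_template(sprintf("g%04d", i)))
      chrom_of <- rep(names(chroms), length.out = n_genes)
      margin <- 500L
      for (cn in names(chroms)) {
        idx <- which(chrom_of == cn)
        if (length(idx) == 0) next
        lens <- vapply(tpl[idx], function(t) nchar(t$seq), integer(1))
        k <- length(idx)
        need <- sum(lens) + (k + 1L) * margin
        if (need > chrom_len)
          stop("cannot pack ", k, " genes of total length ", sum(lens),
               " into a ", chrom_len, " bp chromosome")
        slack <- chrom_len - need
        cuts <- diff(c(0, sort(runif(k)), 1))
        extra <- floor(cuts * slack)
        pos <- margin + extra[1]
        for (j in seq_len(k)) {
          t <- tpl[[idx[j]]]
          strand <- sample(c("+", "-"), 1)
          loc <- orient_gene(t, strand)
          chroms[[cn]] <- splice0(chroms[[cn]], pos, pos + nchar(loc$seq),
                                  loc$seq)
          genes <- rbind(genes, data.frame(
            gene_id = t$gene_id, chrom = cn, strand = strand,
            start = pos, end = pos + nchar(loc$seq),
            exons = I(list(loc$exons + pos))))
          pos <- pos + nchar(loc$seq) + margin + extra[j + 1]
        }
      }
    }
    annotated_genome(genome_id, chroms, genes)
  })
}

# A gene template: CDS split into >=2 exons separated by introns, built in
# forward orientation. Exon coordinates are relative to the locus start.
make_gene_template <- function(gene_id, n_codons = NULL, n_exons = NULL) {
  n_codons <- n_codons %||% sample(80:250, 1)
  n_exons <- n_exons %||% sample(2:4, 1)
  codons <- c("ATG",
              sample(setdiff(all_codons(), c("TAA", "TAG", "TGA")),
                     n_codons - 2, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1))
  cds <- paste(codons, collapse = "")
  cds_len <- nchar(cds)
  # split CDS into exon pieces of >= 30 bp
  repeat {
    cuts <- sort(sample(30:(cds_len - 30), n_exons - 1))
    pieces <- diff(c(0, cuts, cds_len))
    if (all(pieces >= 30)) break
  }
  introns <- vapply(seq_len(n_exons - 1),
                    function(i) random_dna(sample(80:400, 1)), character(1))
  seq <- ""
  exons <- matrix(0L, n_exons, 2, dimnames = list(NULL, c("start", "end")))
  off <- 0L
  cds_off <- c(0L, cumsum(pieces))
  for (i in seq_len(n_exons)) {
    piece <- substring(cds, cds_off[i] + 1, cds_off[i + 1])
    exons[i, ] <- c(off, off + nchar(piece))
    seq <- paste0(seq, piece)
    off <- off + nchar(piece)
    if (i < n_exons) {
      seq <- paste0(seq, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  list(gene_id = gene_id, seq = seq, exons = exons, cds = cds)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# orient a forward-built gene template onto a strand; exon coords stay in
# genomic (forward) order
orient_gene <- function(tpl, strand) {
  if (strand == "+") return(list(seq = tpl$seq, exons = tpl$exons))
  L <- nchar(tpl$seq)
  ex <- cbind(start = L - tpl$exons[, 2], end = L - tpl$exons[, 1])
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  list(seq = revcomp(tpl$seq), exons = ex)
}

#' Sample non-overlapping SV events on a backbone genome
#'
#' Events are placed in intergenic space, separated from genes and from
#' each other, so planted truth sets have unique, SNP-free flanks. Lengths
#' are drawn log-uniformly between `min_len` and `max_len`; inversions and
#' translocations get at least `min_rearrange_len`. DIV (divergent allele)
#' events are length-neutral: the replaced and replacement sequences have
#' equal length. DUP events are tandem duplications; TRA events are
#' cut-and-paste translocations with a destination locus.
#'
#' @param backbone an [annotated_genome()].
#' @param n number of events.
#' @param types vector of event types to cycle through; subset of
#'   `c("INS","DEL","DIV","INV","DUP","TRA")`.
#' @param min_len,max_len SV length range in bp (log-uniform).
#' @param min_rearrange_len minimum length for INV/TRA events.
#' @param min_gap minimum distance between events (and to genes).
#' @param seed RNG seed.
#' @return data.frame of events with columns `event_id`, `type`, `chrom`,
#'   `pos`, `length`, `inserted_seq`, `dest_chrom`, `dest_pos`.
#' @export
sample_sv_events <- function(backbone, n,
                             types = c("INS", "DEL", "DIV"),
                             min_len = 50, max_len = 10000,
                             min_rearrange_len = 1000,
                             min_gap = 2000, seed = 1) {
  stopifnot(n >= 0, min_len >= 50, max_len >= min_len)
  with_seed(seed, {
    occupied <- lapply(backbone$chromosomes, function(s) {
      matrix(numeric(0), 0, 2)
    })
    for (i in seq_len(nrow(backbone$genes))) {
      gr <- backbone$genes[i, ]
      occupied[[gr$chrom]] <- rbind(occupied[[gr$chrom]],
                                    c(gr$start, gr$end))
    }
    clens <- nchar(backbone$chromosomes)
    type_seq <- rep(types, length.out = n)
    rows <- list()
    reserve <- function(chrom, s, e) {
      occupied[[chrom]] <<- rbind(occupied[[chrom]], c(s, e))
    }
    is_free <- function(chrom, s, e) {
      occ <- occupied[[chrom]]
      s2 <- s - min_gap; e2 <- e + min_gap
      !any(occ[, 1] < e2 & occ[, 2] > s2)
    }
    pick_locus <- function(width, exclude_chrom = NULL) {
      for (try in 1:500) {
        cn <- sample(names(clens), 1)
        if (!is.null(exclude_chrom) && length(clens) > 1 &&
            cn == exclude_chrom) next
        if (clens[[cn]] < width + 2 * min_gap) next
        p <- sample.int(clens[[cn]] - width - 2 * min_gap, 1) + min_gap
        if (is_free(cn, p, p + width)) return(list(chrom = cn, pos = p))
      }
      stop("could not place event of width ", width,
           "; genome too crowded for the requested event set")
    }
    for (i in seq_len(n)) {
      ty <- type_seq[i]
      lmin <- if (ty %in% c("INV", "TRA")) max(min_len, min_rearrange_len)
              else min_len
      len <- round(exp(runif(1, log(lmin), log(max(max_len, lmin)))))
      width <- if (ty == "INS") 0 else len
      loc <- pick_locus(width)
      reserve(loc$chrom, loc$pos, loc$pos + width)
      dest_chrom <- NA_character_; dest_pos <- NA_real_
      if (ty == "TRA") {
        d <- pick_locus(0, exclude_chrom = loc$chrom)
        reserve(d$chrom, d$pos, d$pos)
        dest_chrom <- d$chrom; dest_pos <- d$pos
      }
      ins <- ""
      if (ty == "INS" || ty == "DIV") ins <- random_dna(len)
      rows[[i]] <- data.frame(
        event_id = sprintf("sv%04d", i), type = ty, chrom = loc$chrom,
        pos = loc$pos, length = len, inserted_seq = ins,
        dest_chrom = dest_chrom, dest_pos = dest_pos)
    }
    if (length(rows) == 0) return(empty_events())
    do.call(rbind, rows)
  })
}

empty_events <- function() {
  data.frame(event_id = character(), type = character(), chrom = character(),
             pos = numeric(), length = numeric(), inserted_seq = character(),
             dest_chrom = character(), dest_pos = numeric())
}

# width of the backbone interval an event consumes
event_ref_width <- function(ev) ifelse(ev$type == "INS", 0, ev$length)

validate_events <- function(backbone, events) {
  if (nrow(events) == 0) return(invisible(events))
  stopifnot(all(events$type %in% c("INS", "DEL", "DIV", "INV", "DUP", "TRA")))
  if (any(events$length < 1)) stop("event length must be >= 1")
  ins_like <- events$type %in% c("INS", "DIV")
  if (any(ins_like & nchar(events$inserted_seq) != events$length))
    stop("INS/DIV events need inserted_seq of the stated length")
  clens <- nchar(backbone$chromosomes)
  if (!all(events$chrom %in% names(clens)))
    stop("event on unknown chromosome")
  w <- event_ref_width(events)
  if (any(events$pos < 0 | events$pos + w > clens[events$chrom]))
    stop("event interval outside chromosome")
  tra <- events$type == "TRA"
  if (any(tra & (is.na(events$dest_chrom) | is.na(events$dest_pos))))
    stop("TRA events need dest_chrom/dest_pos")
  # non-overlap of backbone footprints (ref spans + TRA destinations)
  foot <- data.frame(id = events$event_id, chrom = events$chrom,
                     s = events$pos, e = events$pos + pmax(w, 1))
  if (any(tra)) {
    foot <- rbind(foot, data.frame(id = events$event_id[tra],
                                   chrom = events$dest_chrom[tra],
                                   s = events$dest_pos[tra],
                                   e = events$dest_pos[tra] + 1))
  }
  for (cn in unique(foot$chrom)) {
    f <- foot[foot$chrom == cn, ]
    f <- f[order(f$s), ]
    if (nrow(f) > 1) {
      bad <- which(f$s[-1] < f$e[-nrow(f)])
      if (length(bad) > 0)
        stop("overlapping events on ", cn, ": ", f$id[bad[1]], " and ",
             f$id[bad[1] + 1])
    }
  }
  invisible(events)
}

# events may not disrupt coding sequence: DEL/DIV fully inside a gene must
# sit within one intron; no event footprint may intersect an exon; INV, DUP
# and TRA donors may not touch gene bodies at all
validate_events_vs_genes <- function(backbone, events) {
  if (nrow(events) == 0 || nrow(backbone$genes) == 0)
    return(invisible(events))
  w <- event_ref_width(events)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    genes <- backbone$genes[backbone$genes$chrom == ev$chrom, ]
    if (nrow(genes) == 0) next
    s <- ev$pos; e <- ev$pos + w[i]
    hit <- which(genes$start < max(e, s + 1) & genes$end > s)
    if (length(hit) == 0) next
    if (ev$type %in% c("INV", "DUP", "TRA"))
      stop("event ", ev$event_id, " (", ev$type, ") intersects gene ",
           genes$gene_id[hit[1]])
    for (h in hit) {
      ex <- genes$exons[[h]]
      if (any(ex[, 1] < e & ex[, 2] > s) ||
          (ev$type == "INS" && any(ev$pos > ex[, 1] & ev$pos < ex[, 2])))
        stop("event ", ev$event_id, " intersects an exon of gene ",
             genes$gene_id[h])
      if (s < genes$start[h] || e > genes$end[h])
        stop("event ", ev$event_id, " straddles a boundary of gene ",
             genes$gene_id[h])
    }
  }
  invisible(events)
}

#' Derive an accession genome from a backbone by applying SV events
#'
#' Applies the events right-to-left per chromosome, adds SNP noise outside
#' planted breakpoints, drops lost genes from the annotation and (optionally)
#' gains novel genes by length-neutral replacement of intergenic sequence.
#' Gene models are remapped through the events, so e.g. a deletion fully
#' inside an intron leaves the gene present with an identical CDS.
#'
#' @param backbone an [annotated_genome()].
#' @param events data.frame of SV events as from [sample_sv_events()];
#'   events must be non-overlapping on the backbone.
#' @param gene_loss gene ids to drop from the derived annotation
#'   (annotation-level loss; the locus sequence remains).
#' @param snp_rate per-bp substitution probability; SNPs are never placed
#'   within `breakpoint_guard` bp of a planted breakpoint, keeping truth
#'   sets unambiguous for recall tests.
#' @param seed RNG seed.
#' @param genome_id name for the derived genome.
#' @param gene_gain number of novel genes to gain (planted as length-neutral
#'   DIV events in intergenic space, recorded in the truth set).
#' @param breakpoint_guard half-width of the SNP-free zone around
#'   breakpoints, in bp.
#' @return list with elements `genome` (the derived [annotated_genome()])
#'   and `truth` (a `truth_set`: `genome_id`, `events`, `lost_gene_ids`,
#'   `gained_gene_ids`).
#' @export
derive_accession <- function(backbone, events = empty_events(),
                             gene_loss = character(), snp_rate = 0,
                             seed = 1, genome_id = NULL, gene_gain = 0,
                             breakpoint_guard = 100) {
  genome_id <- genome_id %||% paste0(backbone$genome_id, "_derived")
  events <- as.data.frame(events)
  if (nrow(events) > 0 && is.null(events$dest_chrom)) {
    events$dest_chrom <- NA_character_; events$dest_pos <- NA_real_
  }
  validate_events(backbone, events)
  validate_events_vs_genes(backbone, events)
  if (!all(gene_loss %in% backbone$genes$gene_id))
    stop("gene_loss contains unknown gene ids")
  with_seed(seed, {
    gained <- character()
    # plant gained genes as length-neutral intergenic replacements
    if (gene_gain > 0) {
      for (gi in seq_len(gene_gain)) {
        tpl <- make_gene_template(sprintf("%s_gain%02d", genome_id, gi))
        strand <- sample(c("+", "-"), 1)
        loc <- orient_gene(tpl, strand)
        glen <- nchar(loc$seq)
        placed <- FALSE
        for (try in 1:500) {
          cn <- sample(names(backbone$chromosomes), 1)
          cl <- nchar(backbone$chromosomes[[cn]])
          if (cl < glen + 2000) next
          p <- sample.int(cl - glen - 2000, 1) + 1000
          trial <- data.frame(event_id = paste0("gain_", tpl$gene_id),
                              type = "DIV", chrom = cn, pos = p,
                              length = glen, inserted_seq = loc$seq,
                              dest_chrom = NA_character_,
                              dest_pos = NA_real_)
          ok <- tryCatch({
            validate_events(backbone, rbind(events, trial))
            validate_events_vs_genes(backbone, trial)
            TRUE
          }, error = function(e) FALSE)
          if (ok) {
            events <- rbind(events, trial)
            attr(events, "gain_meta") <- c(attr(events, "gain_meta"),
              setNames(list(list(gene_id = tpl$gene_id, chrom = cn, pos = p,
                                 strand = strand, exons = loc$exons)),
                       tpl$gene_id))
            gained <- c(gained, tpl$gene_id)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place gained gene ", tpl$gene_id)
      }
    }
    chroms <- backbone$chromosomes
    w <- event_ref_width(events)

    # SNP noise, outside event footprints +/- guard
    if (snp_rate > 0) {
      for (cn in names(chroms)) {
        cl <- nchar(chroms[[cn]])
        blocked <- rep(FALSE, cl)
        if (nrow(events) > 0) {
          on_c <- which(events$chrom == cn)
          for (i in on_c) {
            s <- max(1, events$pos[i] - breakpoint_guard + 1)
            e <- min(cl, events$pos[i] + w[i] + breakpoint_guard)
            blocked[s:e] <- TRUE
          }
          dn <- which(!is.na(events$dest_chrom) & events$dest_chrom == cn)
          for (i in dn) {
            s <- max(1, events$dest_pos[i] - breakpoint_guard + 1)
            e <- min(cl, events$dest_pos[i] + breakpoint_guard)
            blocked[s:e] <- TRUE
          }
        }
        cand <- which(!blocked)
        n_snp <- rbinom(1, length(cand), snp_rate)
        if (n_snp > 0) {
          pos <- sample(cand, n_snp)
          old <- substring(chroms[[cn]], pos, pos)
          new <- vapply(old, function(b)
            sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1),
            character(1), USE.NAMES = FALSE)
          v <- strsplit(chroms[[cn]], "")[[1]]
          v[pos] <- new
          chroms[[cn]] <- paste(v, collapse = "")
        }
      }
    }

    # build edit operations (0-based [start, end) -> replacement)
    ops <- list()
    if (nrow(events) > 0) {
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        seg <- subseq0(chroms[[ev$chrom]], ev$pos, ev$pos + w[i])
        op <- switch(ev$type,
          INS = list(list(ev$chrom, ev$pos, ev$pos, ev$inserted_seq)),
          DEL = list(list(ev$chrom, ev$pos, ev$pos + ev$length, "")),
          DIV = list(list(ev$chrom, ev$pos, ev$pos + ev$length,
                          ev$inserted_seq)),
          INV = list(list(ev$chrom, ev$pos, ev$pos + ev$length,
                          revcomp(seg))),
          DUP = list(list(ev$chrom, ev$pos + ev$length, ev$pos + ev$length,
                          seg)),
          TRA = list(list(ev$chrom, ev$pos, ev$pos + ev$length, ""),
                     list(ev$dest_chrom, ev$dest_pos, ev$dest_pos, seg)))
        ops <- c(ops, op)
      }
    }
    by_chrom <- split(ops, vapply(ops, `[[`, character(1), 1))
    for (cn in names(by_chrom)) {
      ol <- by_chrom[[cn]]
      ord <- order(vapply(ol, `[[`, numeric(1), 2), decreasing = TRUE)
      for (o in ol[ord]) {
        chroms[[cn]] <- splice0(chroms[[cn]], o[[2]], o[[3]], o[[4]])
      }
    }

    # remap gene models through the events
    genes <- backbone$genes
    genes <- genes[!(genes$gene_id %in% gene_loss), , drop = FALSE]
    offset_of <- function(chrom, x) {
      if (nrow(events) == 0) return(x * 0)
      delta <- rep(0, nrow(events))
      delta[events$type == "INS"] <- events$length[events$type == "INS"]
      delta[events$type == "DEL"] <- -events$length[events$type == "DEL"]
      delta[events$type == "DUP"] <- events$length[events$type == "DUP"]
      delta[events$type == "TRA"] <- -events$length[events$type == "TRA"]
      off <- vapply(x, function(xx) {
        on_c <- events$chrom == chrom & (events$pos + w) <= xx
        d <- sum(delta[on_c])
        dn <- !is.na(events$dest_chrom) & events$dest_chrom == chrom &
          events$type == "TRA" & events$dest_pos <= xx
        d + sum(events$length[dn])
      }, numeric(1))
      off
    }
    if (nrow(genes) > 0) {
      for (i in seq_len(nrow(genes))) {
        ex <- genes$exons[[i]]
        cn <- genes$chrom[i]
        ex2 <- cbind(start = ex[, 1] + offset_of(cn, ex[, 1]),
                     end = ex[, 2] + offset_of(cn, ex[, 2]))
        genes$exons[[i]] <- ex2
        genes$start[i] <- min(ex2[, 1])
        genes$end[i] <- max(ex2[, 2])
      }
    }
    gm <- attr(events, "gain_meta")
    for (gid in gained) {
      m <- gm[[gid]]
      ex <- m$exons + m$pos
      ex2 <- cbind(start = ex[, 1] + offset_of(m$chrom, ex[, 1]),
                   end = ex[, 2] + offset_of(m$chrom, ex[, 2]))
      genes <- rbind(genes, data.frame(
        gene_id = gid, chrom = m$chrom, strand = m$strand,
        start = min(ex2[, 1]), end = max(ex2[, 2]), exons = I(list(ex2))))
    }
    truth_events <- events
    attr(truth_events, "gain_meta") <- NULL
    truth <- structure(list(genome_id = genome_id, events = truth_events,
                            lost_gene_ids = gene_loss,
                            gained_gene_ids = gained),
                       class = "truth_set")
    list(genome = annotated_genome(genome_id, chroms, genes), truth = truth)
  })
}

#' Write a truth set as a BED-like TSV
#'
#' Columns: chrom, start, end (backbone coordinates), type, length,
#' event_id.
#'
#' @param truth a `truth_set` from [derive_accession()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  ev <- truth$events
  w <- event_ref_width(ev)
  df <- data.frame(chrom = ev$chrom, start = ev$pos, end = ev$pos + w,
                   type = ev$type, length = ev$length,
                   event_id = ev$event_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a short-read set from a genome
#'
#' Uniform single-end reads from both strands with iid substitution errors.
#' The expected read count is `depth * genome_length / read_len`, realized
#' per chromosome by rounding. Deterministic per seed.
#'
#' @param genome an [annotated_genome()].
#' @param read_len read length in bp (must not exceed the shortest
#'   chromosome).
#' @param depth fold coverage (> 0).
#' @param err_rate per-bp substitution error probability.
#' @param seed RNG seed.
#' @return data.frame with columns `read_id`, `seq`.
#' @export
simulate_reads <- function(genome, read_len = 100, depth = 20,
                           err_rate = 0, seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  clens <- nchar(genome$chromosomes)
  if (read_len > min(clens))
    stop("read_len exceeds the shortest chromosome")
  with_seed(seed, {
    all_seq <- character(); all_id <- character()
    for (cn in names(clens)) {
      n_reads <- round(depth * clens[[cn]] / read_len)
      if (n_reads == 0) next
      starts <- sample.int(clens[[cn]] - read_len + 1, n_reads,
                           replace = TRUE)
      seqs <- substring(genome$chromosomes[[cn]], starts,
                        starts + read_len - 1)
      rc <- runif(n_reads) < 0.5
      seqs[rc] <- revcomp(seqs[rc])
      all_seq <- c(all_seq, seqs)
      all_id <- c(all_id, sprintf("%s_%s_r%06d", genome$genome_id, cn,
                                  seq_len(n_reads)))
    }
    if (err_rate > 0) all_seq <- .mutate_reads_cpp(all_seq, err_rate)
    data.frame(read_id = all_id, seq = all_seq)
  })
}

#' Simulate a gene presence/absence panel of genomes
#'
#' Builds `n_genomes` annotated genomes from a shared pool of gene
#' templates laid out in a common (collinear) order, with planted
#' core/dispensable/private occupancy and per-genome SNP divergence. This
#' is the truth-bearing input for the syntelog pangenome pipeline: class
#' labels are known by construction.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_core genes present in all genomes.
#' @param n_disp genes present in 2..(n_genomes-1) genomes.
#' @param n_priv genes present in exactly one genome.
#' @param seed RNG seed.
#' @param snp_rate per-bp substitution rate applied independently per
#'   genome copy of each gene.
#' @param spacer intergenic spacer length between genes, bp.
#' @return list with `genomes` (list of [annotated_genome()]) and `truth`
#'   (data.frame: `gene_id`, `class`, `n_genomes`, and one presence column
#'   per genome).
#' @export
simulate_gene_panel <- function(n_genomes = 4, n_core = 200, n_disp = 60,
                                n_priv = 40, seed = 1, snp_rate = 0.002,
                                spacer = 400) {
  stopifnot(n_genomes >= 2)
  with_seed(seed, {
    n_tot <- n_core + n_disp + n_priv
    tpl <- lapply(seq_len(n_tot), function(i)
      make_gene_template(sprintf("g%04d", i)))
    cls <- c(rep("core", n_core), rep("dispensable", n_disp),
             rep("private", n_priv))
    gnames <- paste0("genome", seq_len(n_genomes))
    presence <- matrix(FALSE, n_tot, n_genomes,
                       dimnames = list(vapply(tpl, `[[`, character(1),
                                              "gene_id"), gnames))
    presence[cls == "core", ] <- TRUE
    occ_choices <- 2:(n_genomes - 1)
    for (i in which(cls == "dispensable")) {
      k <- occ_choices[sample.int(length(occ_choices), 1)]
      presence[i, sample(n_genomes, k)] <- TRUE
    }
    priv_idx <- which(cls == "private")
    for (j in seq_along(priv_idx)) {
      presence[priv_idx[j], ((j - 1) %% n_genomes) + 1] <- TRUE
    }
    ord <- sample(n_tot)  # shared gene order across genomes
    strands <- sample(c("+", "-"), n_tot, replace = TRUE)
    genomes <- lapply(seq_len(n_genomes), function(gi) {
      keep <- ord[presence[ord, gi]]
      seqs <- character(); genes <- empty_genes()
      pos <- spacer
      pieces <- character(0)
      pieces <- c(pieces, random_dna(spacer))
      for (ti in keep) {
        t <- tpl[[ti]]
        gseq <- t$seq
        if (snp_rate > 0) {
          n_snp <- rbinom(1, nchar(gseq), snp_rate)
          if (n_snp > 0) {
            p <- sample.int(nchar(gseq), n_snp)
            v <- strsplit(gseq, "")[[1]]
            v[p] <- vapply(v[p], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
              USE.NAMES = FALSE)
            gseq <- paste(v, collapse = "")
          }
        }
        loc <- orient_gene(list(seq = gseq, exons = t$exons), strands[ti])
        pieces <- c(pieces, loc$seq, random_dna(spacer))
        genes <- rbind(genes, data.frame(
          gene_id = t$gene_id, chrom = "chr1", strand = strands[ti],
          start = pos, end = pos + nchar(loc$seq),
          exons = I(list(loc$exons + pos))))
        pos <- pos + nchar(loc$seq) + spacer
      }
      annotated_genome(gnames[gi],
                       c(chr1 = paste(pieces, collapse = "")), genes)
    })
    truth <- data.frame(gene_id = rownames(presence), class = cls,
                        n_genomes = rowSums(presence))
    truth <- cbind(truth, as.data.frame(presence))
    list(genomes = genomes, truth = truth)
  })
}

#' Population specification for genotype simulation
#'
#' @param populations named integer vector: accessions per population.
#' @param freq numeric matrix of alternate-allele frequencies,
#'   sites x populations (column names must match `names(populations)`).
#' @param missing_rate probability that any genotype entry is missing.
#' @param seed RNG seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(populations, freq, missing_rate = 0, seed = 1) {
  freq <- as.matrix(freq)
  stopifnot(all(populations >= 1), all(freq >= 0 & freq <= 1),
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(colnames(freq))) colnames(freq) <- names(populations)
  if (!setequal(colnames(freq), names(populations)))
    stop("freq columns must match population names")
  structure(list(populations = populations,
                 freq = freq[, names(populations), drop = FALSE],
                 missing_rate = missing_rate, seed = seed),
            class = "population_spec")
}

#' Simulate a population genotype matrix from allele frequencies
#'
#' Diploid genotypes are drawn per accession as Binomial(2, f_pop) at each
#' site; entries are then masked independently at the missing rate.
#'
#' @param spec a [population_spec()].
#' @param sv_ids site identifiers (rownames of `spec$freq` used if NULL).
#' @return list with `gm` (an `sv_genotypes` object, see
#'   [sv_genotypes()]) and `pops` (data.frame `accession`, `population`).
#' @export
simulate_population_genotypes <- function(spec, sv_ids = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  sv_ids <- sv_ids %||% rownames(spec$freq) %||%
    sprintf("sv%04d", seq_len(nrow(spec$freq)))
  if (length(sv_ids) != nrow(spec$freq))
    stop("sv_ids length must match freq rows")
  with_seed(spec$seed, {
    acc <- character(); popv <- character()
    for (pn in names(spec$populations)) {
      n <- spec$populations[[pn]]
      acc <- c(acc, sprintf("%s_%03d", pn, seq_len(n)))
      popv <- c(popv, rep(pn, n))
    }
    n_site <- length(sv_ids); n_acc <- length(acc)
    dos <- matrix(NA_integer_, n_site, n_acc,
                  dimnames = list(sv_ids, acc))
    for (j in seq_len(n_acc)) {
      f <- spec$freq[, popv[j]]
      dos[, j] <- rbinom(n_site, 2, f)
    }
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n_site * n_acc) < spec$missing_rate,
                     n_site, n_acc)
      dos[miss] <- NA_integer_
    }
    sites <- data.frame(site_id = sv_ids, chrom = "chr1",
                        pos = seq_len(n_site) * 1000,
                        end = seq_len(n_site) * 1000 + 1,
                        type = "INS")
    gm <- sv_genotypes(dos, sites)
    list(gm = gm, pops = data.frame(accession = acc, population = popv))
  })
}

#' Simulate a diploid accession panel with reads for SV genotyping
#'
#' For each accession, per-site diploid genotypes are drawn as
#' Binomial(2, f); the two haplotype genomes are built by applying the
#' carried subset of events to the backbone, and reads are simulated from
#' each haplotype at half the requested depth.
#'
#' @param backbone an [annotated_genome()].
#' @param events planted biallelic SV events (as from [sample_sv_events()],
#'   INS/DEL/DIV types).
#' @param n_accessions number of accessions.
#' @param freq per-site alternate allele frequency (recycled).
#' @param depth total fold coverage per accession.
#' @param read_len read length, bp.
#' @param err_rate per-bp read error rate.
#' @param seed RNG seed.
#' @return list with `reads` (list of read data.frames per accession),
#'   `genotypes` (true dosage matrix, sites x accessions) and
#'   `accessions`.
#' @export
simulate_sv_panel <- function(backbone, events, n_accessions = 20,
                              freq = 0.5, depth = 20, read_len = 100,
                              err_rate = 0.002, seed = 1) {
  freq <- rep_len(freq, nrow(events))
  with_seed(seed, {
    acc <- sprintf("acc%03d", seq_len(n_accessions))
    truth <- matrix(0L, nrow(events), n_accessions,
                    dimnames = list(events$event_id, acc))
    reads <- vector("list", n_accessions)
    names(reads) <- acc
    sub_seeds <- sample.int(.Machine$integer.max / 2, n_accessions * 3)
    for (j in seq_len(n_accessions)) {
      dos <- rbinom(nrow(events), 2, freq)
      truth[, j] <- dos
      hap_ev <- list(events[dos >= 1, , drop = FALSE],
                     events[dos == 2, , drop = FALSE])
      rr <- list()
      for (h in 1:2) {
        d <- derive_accession(backbone, hap_ev[[h]],
                              seed = sub_seeds[(j - 1) * 3 + h],
                              genome_id = sprintf("%s_h%d", acc[j], h))
        rr[[h]] <- simulate_reads(d$genome, read_len, depth / 2, err_rate,
                                  seed = sub_seeds[(j - 1) * 3 + 3] + h)
      }
      reads[[j]] <- rbind(rr[[1]], rr[[2]])
    }
    list(reads = reads, genotypes = truth, accessions = acc)
  })
}
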