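#' Iteratively build a linear pangenome
#'
#' Starting from the backbone (ref0), each genome in turn is aligned
#' against the current pan sequence; insertions of at least `min_ins` bp
#' are spliced in at their breakpoints to produce the next reference, the
#' insertion registry is updated and the liftover maps extended. Later
#' genomes align against the updated pan, so an insertion shared by
#' several genomes is integrated exactly once. Divergent-allele (DIV)
#' variants contribute their alternative sequence as an insertion and
#' their reference span as a catalogued deletion. Deletions,
#' duplications, inversions and translocations are catalogued but never
#' spliced.
#'
#' @param backbone an [annotated_genome()] (ref0).
#' @param others list of [annotated_genome()] objects, integration order =
#'   list order.
#' @param min_ins minimum integrated insertion length, bp.
#' @param ... passed to [genome_pair_variants()].
#' @return A `linear_pan` object: `pan` (named character vector of pan
#'   chromosome sequences), `registry` (data.frame of integrated
#'   insertions with final pan coordinates `pan_start`/`pan_end`, source
#'   genome and interval, `iteration`), `variants` (per-iteration raw
#'   variant tables in the coordinates of the pan they were called
#'   against), `backbone_id`, `genomes`.
#' @export
build_linear_pan <- function(backbone, others, min_ins = 50, ...) {
  pan <- backbone$chromosomes
  registry <- data.frame(chrom = character(), pan_start = numeric(),
                         pan_end = numeric(), length = numeric(),
                         source_genome = character(),
                         source_chrom = character(),
                         source_start = numeric(), source_end = numeric(),
                         iteration = integer(), seq = character())
  per_iter <- list()
  for (it in seq_along(others)) {
    g <- others[[it]]
    cur <- annotated_genome(sprintf("pan_ref%d", it - 1), pan)
    pv <- genome_pair_variants(cur, g, min_sv = min_ins, ...)
    per_iter[[it]] <- pv
    ins <- pv[pv$type %in% c("INS", "DIV") & nchar(pv$seq) >= min_ins, ,
              drop = FALSE]
    if (nrow(ins) == 0) next
    # splice right-to-left; ties at one breakpoint resolved longest-first
    ins <- ins[order(ins$ref_chrom, -ins$ref_start, -nchar(ins$seq)), ,
               drop = FALSE]
    for (i in seq_len(nrow(ins))) {
      v <- ins[i, ]
      at <- if (v$type == "DIV") v$ref_end else v$ref_start
      len <- nchar(v$seq)
      pan[[v$ref_chrom]] <- splice0(pan[[v$ref_chrom]], at, at, v$seq)
      # shift existing registry entries right of the splice point
      onc <- registry$chrom == v$ref_chrom & registry$pan_start >= at
      registry$pan_start[onc] <- registry$pan_start[onc] + len
      registry$pan_end[onc] <- registry$pan_end[onc] + len
      registry <- rbind(registry, data.frame(
        chrom = v$ref_chrom, pan_start = at, pan_end = at + len,
        length = len, source_genome = g$genome_id,
        source_chrom = v$qry_chrom, source_start = v$qry_start,
        source_end = v$qry_end, iteration = it, seq = v$seq))
    }
  }
  registry <- registry[order(registry$chrom, registry$pan_start), ,
                       drop = FALSE]
  rownames(registry) <- NULL
  structure(list(pan = pan, registry = registry, variants = per_iter,
                 backbone_id = backbone$genome_id,
                 backbone_len = nchar(backbone$chromosomes),
                 genomes = vapply(others, `[[`, character(1),
                                  "genome_id")),
            class = "linear_pan")
}

#' @export
print.linear_pan <- function(x, ...) {
  cat(sprintf(paste0("<linear_pan> %s + %d genome(s): %s bp pan, ",
                     "%d registered insertion(s), +%s bp over backbone\n"),
              x$backbone_id, length(x$genomes),
              format(sum(nchar(x$pan)), big.mark = ","),
              nrow(x$registry),
              format(sum(x$registry$length), big.mark = ",")))
  invisible(x)
}

# registry insertions added after a given stage, with their positions
# expressed in that stage's coordinates
later_insertions <- function(pan, chrom, stage) {
  reg <- pan$registry
  reg <- reg[reg$chrom == chrom & reg$iteration > stage, , drop = FALSE]
  reg <- reg[order(reg$pan_start), , drop = FALSE]
  if (nrow(reg) == 0) return(reg)
  shift <- c(0, cumsum(reg$length))[seq_len(nrow(reg))]
  reg$stage_pos <- reg$pan_start - shift
  reg
}

#' Lift a coordinate from an intermediate reference to the final pan
#'
#' Maps a position on ref_`stage` (stage 0 = backbone) to the final pan
#' coordinate system by adding the lengths of insertions integrated at
#' later iterations before that position. Strictly monotone within a
#' chromosome.
#'
#' @param pan a `linear_pan`.
#' @param stage reference stage the coordinates live on (0 = backbone).
#' @param chrom chromosome name.
#' @param coord numeric vector of 0-based positions on ref_`stage`.
#' @return numeric vector of pan positions.
#' @export
liftover <- function(pan, stage, chrom, coord) {
  reg <- later_insertions(pan, chrom, stage)
  vapply(coord, function(x) {
    x + sum(reg$length[reg$stage_pos <= x])
  }, numeric(1))
}

#' Map a final pan coordinate back to an intermediate reference
#'
#' Positions that fall inside an interval inserted after `stage` are
#' unmappable and returned as NA.
#'
#' @inheritParams liftover
#' @param coord numeric vector of 0-based pan positions.
#' @return numeric vector of ref_`stage` positions (NA where unmappable).
#' @export
liftback <- function(pan, stage, chrom, coord) {
  reg <- later_insertions(pan, chrom, stage)
  vapply(coord, function(x) {
    if (nrow(reg) > 0 && any(x >= reg$pan_start & x < reg$pan_end))
      return(NA_real_)
    x - sum(reg$length[reg$pan_end <= x])
  }, numeric(1))
}

#' Remove all registered insertions from the pan sequence
#'
#' The result must equal the backbone byte-exactly (reconstruction
#' invariant).
#'
#' @param pan a `linear_pan`.
#' @return named character vector of chromosome sequences.
#' @export
strip_registry <- function(pan) {
  out <- pan$pan
  reg <- pan$registry
  for (cn in names(out)) {
    r <- reg[reg$chrom == cn, , drop = FALSE]
    r <- r[order(-r$pan_start), , drop = FALSE]
    for (i in seq_len(nrow(r)))
      out[[cn]] <- splice0(out[[cn]], r$pan_start[i], r$pan_end[i], "")
  }
  out
}

#' Collect the linear-pangenome SV catalogue
#'
#' Lifts every iteration's raw variants into final pan coordinates, types
#' them into DEL / BND / INS / DUP / INV, and deduplicates records whose
#' breakpoints agree within `tol` bp with matching type (source genomes
#' are unioned). DIV variants contribute a DEL for their reference span
#' (their alternative sequence lives in the registry as an INS).
#' Registry insertions become INS records. Deletions that exactly match a
#' registry interval are absences of an integrated insertion, not new
#' SVs, and are dropped.
#'
#' @param pan a `linear_pan` from [build_linear_pan()].
#' @param tol breakpoint tolerance for deduplication, bp.
#' @return data.frame of SV records: `sv_id`, `type`, `chrom`, `pos`,
#'   `end` (0-based pan coordinates), `length`, `seq`, `mate_chrom`,
#'   `mate_pos` (BND only), `sources`.
#' @export
collect_linear_svs <- function(pan, tol = 10) {
  recs <- list()
  reg <- pan$registry
  for (i in seq_len(nrow(reg))) {
    recs[[length(recs) + 1]] <- data.frame(
      type = "INS", chrom = reg$chrom[i], pos = reg$pan_start[i],
      end = reg$pan_end[i], length = reg$length[i], seq = reg$seq[i],
      mate_chrom = NA_character_, mate_pos = NA_real_,
      sources = reg$source_genome[i])
  }
  for (it in seq_along(pan$variants)) {
    pv <- pan$variants[[it]]
    if (nrow(pv) == 0) next
    src <- pan$genomes[it]
    for (i in seq_len(nrow(pv))) {
      v <- pv[i, ]
      stage <- it - 1
      p0 <- liftover(pan, stage, v$ref_chrom, v$ref_start)
      p1 <- liftover(pan, stage, v$ref_chrom, v$ref_end)
      if (v$type %in% c("DEL", "DIV")) {
        # absence of an integrated insertion is not a new SV
        hit <- reg$chrom == v$ref_chrom &
          abs(reg$pan_start - p0) <= tol & abs(reg$pan_end - p1) <= tol
        if (v$type == "DEL" && any(hit)) next
        recs[[length(recs) + 1]] <- data.frame(
          type = "DEL", chrom = v$ref_chrom, pos = p0, end = p1,
          length = p1 - p0, seq = "", mate_chrom = NA_character_,
          mate_pos = NA_real_, sources = src)
      } else if (v$type == "INV") {
        recs[[length(recs) + 1]] <- data.frame(
          type = "INV", chrom = v$ref_chrom, pos = p0, end = p1,
          length = p1 - p0, seq = "", mate_chrom = NA_character_,
          mate_pos = NA_real_, sources = src)
      } else if (v$type == "DUP") {
        recs[[length(recs) + 1]] <- data.frame(
          type = "DUP", chrom = v$ref_chrom, pos = p0, end = p1,
          length = p1 - p0, seq = "", mate_chrom = NA_character_,
          mate_pos = NA_real_, sources = src)
      } else if (v$type == "TRA") {
        mate_pos <- if (!is.na(v$dest_pos))
          liftover(pan, stage, v$dest_chrom, v$dest_pos) else NA_real_
        recs[[length(recs) + 1]] <- data.frame(
          type = "BND", chrom = v$ref_chrom, pos = p0, end = p1,
          length = p1 - p0, seq = "", mate_chrom = v$dest_chrom,
          mate_pos = mate_pos, sources = src)
      }
    }
  }
  if (length(recs) == 0)
    return(data.frame(sv_id = character(), type = character(),
                      chrom = character(), pos = numeric(),
                      end = numeric(), length = numeric(),
                      seq = character(), mate_chrom = character(),
                      mate_pos = numeric(), sources = character()))
  out <- do.call(rbind, recs)
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  # deduplicate within tolerance, unioning sources
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (out$type[j] == out$type[i] && out$chrom[j] == out$chrom[i] &&
          abs(out$pos[j] - out$pos[i]) <= tol &&
          abs(out$end[j] - out$end[i]) <= tol) {
        srcs <- unique(c(strsplit(out$sources[j], ",")[[1]],
                         out$sources[i]))
        out$sources[j] <- paste(srcs, collapse = ",")
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$sv_id <- sprintf("lsv%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("sv_id", "type", "chrom", "pos", "end", "length", "seq",
          "mate_chrom", "mate_pos", "sources")]
}

#' Lift backbone gene models onto the pan
#'
#' @param pan a `linear_pan`.
#' @param backbone the backbone [annotated_genome()] the pan grew from.
#' @return the backbone gene table with coordinates lifted to the pan.
#' @export
lift_genes <- function(pan, backbone) {
  genes <- backbone$genes
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    ex <- genes$exons[[i]]
    ex2 <- cbind(start = liftover(pan, 0, cn, ex[, 1]),
                 end = liftover(pan, 0, cn, ex[, 2]))
    genes$exons[[i]] <- ex2
    genes$start[i] <- min(ex2[, 1])
    genes$end[i] <- max(ex2[, 2])
  }
  genes
}

#' Classify new (inserted) pan sequences relative to genes
#'
#' Each registry insertion is labelled `genic` when it overlaps a gene
#' body, `flank_2kb` when it lies within `flank` bp of a gene, and
#' `intergenic` otherwise (precedence genic > flank > intergenic).
#'
#' @param pan a `linear_pan`.
#' @param genes gene models in pan coordinates (see [lift_genes()]).
#' @param flank flank width, bp.
#' @return list with `table` (the registry plus a `placement` column) and
#'   `fractions` (named fractions over the three classes).
#' @export
annotate_new_sequences <- function(pan, genes, flank = 2000) {
  reg <- pan$registry
  placement <- character(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    g <- genes[genes$chrom == reg$chrom[i], , drop = FALSE]
    s <- reg$pan_start[i]; e <- reg$pan_end[i]
    if (nrow(g) > 0 && any(g$start < e & g$end > s)) {
      placement[i] <- "genic"
    } else if (nrow(g) > 0 && any(g$start - flank < e &
                                  g$end + flank > s)) {
      placement[i] <- "flank_2kb"
    } else {
      placement[i] <- "intergenic"
    }
  }
  tab <- cbind(reg[, setdiff(names(reg), "seq")], placement = placement)
  fr <- prop.table(table(factor(placement,
                                levels = c("genic", "flank_2kb",
                                           "intergenic"))))
  list(table = tab, fractions = c(fr))
}

#' Write the linear-pan SV catalogue as VCF 4.2
#'
#' BND records are written as mate pairs with bracketed ALT notation;
#' other types use symbolic alleles with END/SVLEN.
#'
#' @param svs data.frame from [collect_linear_svs()].
#' @param pan a `linear_pan` (for contig headers and padding bases).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_linear_vcf <- function(svs, pan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of reference span\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=SOURCES,Number=.,Type=String,Description=\"Source genomes\">",
               "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
               "##ALT=<ID=DEL,Description=\"Deletion\">",
               "##ALT=<ID=INS,Description=\"Insertion\">",
               "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
               "##ALT=<ID=INV,Description=\"Inversion\">",
               sprintf("##contig=<ID=%s,length=%d>", names(pan$pan),
                       nchar(pan$pan)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(svs))) {
    v <- svs[i, ]
    pad <- subseq0(pan$pan[[v$chrom]], max(v$pos - 1, 0), max(v$pos, 1))
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SOURCES=%s", v$type,
                    as.integer(v$end), as.integer(v$length), v$sources)
    if (v$type == "BND") {
      mate_ref <- subseq0(pan$pan[[v$mate_chrom]], v$mate_pos,
                          v$mate_pos + 1)
      writeLines(sprintf("%s\t%d\t%s_1\t%s\t%s[%s:%d[\t.\tPASS\t%s;MATEID=%s_2",
                         v$chrom, as.integer(v$pos), v$sv_id, pad, pad,
                         v$mate_chrom, as.integer(v$mate_pos) + 1L, info,
                         v$sv_id), con)
      writeLines(sprintf("%s\t%d\t%s_2\t%s\t]%s:%d]%s\t.\tPASS\t%s;MATEID=%s_1",
                         v$mate_chrom, as.integer(v$mate_pos) + 1L,
                         v$sv_id, mate_ref, v$chrom, as.integer(v$pos),
                         mate_ref, info, v$sv_id), con)
    } else {
      writeLines(sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\t%s", v$chrom,
                         as.integer(v$pos), v$sv_id, pad, v$type, info),
                 con)
    }
  }
  invisible(path)
}
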