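#' Build a backbone-anchored pangenome graph
#'
#' Integrates genomes one at a time against the backbone's stable
#' coordinates: every qualifying gap variant (INS/DEL/DIV of at least
#' `min_variant` bp) contributes an alternative allele attached at
#' backbone breakpoints. Alleles whose breakpoints coincide within
#' `breakpoint_tol` bp are merged into one site rather than duplicated.
#' Inversions are deliberately not added to the graph (they are the linear
#' pangenome's job); the backbone path is never altered by integration.
#'
#' @param backbone an [annotated_genome()]; its path anchors the graph.
#' @param others list of [annotated_genome()] objects to integrate, in
#'   order.
#' @param min_variant minimum SV length integrated into the graph, bp.
#' @param breakpoint_tol breakpoint tolerance for merging alleles into one
#'   site, bp.
#' @param ... passed to [genome_pair_variants()] (k, chaining parameters).
#' @return A `pan_graph` object: `nodes` (data.frame `node_id`, `seq`,
#'   `chrom`, `start`, `end` - stable backbone interval, NA for
#'   alternative-allele nodes - and `origin`), `edges`, `paths` (genome ->
#'   chromosome -> node id walk), `sites` (per-site allele table) and
#'   `genomes`.
#' @export
build_graph <- function(backbone, others, min_variant = 50,
                        breakpoint_tol = 10, ...) {
  variants <- list()
  for (g in others) {
    pv <- genome_pair_variants(backbone, g, min_sv = min_variant, ...)
    pv <- pv[pv$type %in% c("INS", "DEL", "DIV"), , drop = FALSE]
    if (nrow(pv) > 0) {
      pv$genome <- g$genome_id
      variants[[length(variants) + 1]] <- pv
    }
  }
  allv <- if (length(variants) > 0) do.call(rbind, variants)
          else cbind(empty_pair_variants(), genome = character())

  # merge variants into sites by breakpoint proximity
  sites <- list()
  if (nrow(allv) > 0) {
    allv <- allv[order(allv$ref_chrom, allv$ref_start, allv$ref_end), ]
    cur <- NULL
    flush <- function() if (!is.null(cur)) sites[[length(sites) + 1]] <<- cur
    for (i in seq_len(nrow(allv))) {
      v <- allv[i, ]
      if (!is.null(cur) && v$ref_chrom == cur$chrom &&
          abs(v$ref_start - cur$ref_start) <= breakpoint_tol &&
          abs(v$ref_end - cur$ref_end) <= breakpoint_tol) {
        cur$alleles[[length(cur$alleles) + 1]] <- list(
          genome = v$genome, seq = v$seq)
      } else {
        flush()
        cur <- list(chrom = v$ref_chrom, ref_start = v$ref_start,
                    ref_end = v$ref_end,
                    alleles = list(list(genome = v$genome, seq = v$seq)))
      }
    }
    flush()
  }

  # drop sites overlapping an earlier site on the backbone (outermost wins)
  keep <- logical(length(sites))
  last_end <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    le <- last_end[[s$chrom]] %||% -1
    keep[i] <- s$ref_start >= le
    if (keep[i]) last_end[[s$chrom]] <- max(le, s$ref_end)
  }
  sites <- sites[keep]

  # segment the backbone at site boundaries and build nodes
  nodes <- data.frame(node_id = integer(), seq = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), origin = character())
  nid <- 0L
  new_node <- function(seq, chrom, start, end, origin) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(node_id = nid, seq = seq,
                                      chrom = chrom, start = start,
                                      end = end, origin = origin))
    nid
  }
  genome_ids <- c(backbone$genome_id,
                  vapply(others, `[[`, character(1), "genome_id"))
  paths <- setNames(lapply(genome_ids, function(g)
    setNames(vector("list", length(backbone$chromosomes)),
             names(backbone$chromosomes))), genome_ids)
  site_tab <- list()

  for (cn in names(backbone$chromosomes)) {
    cs <- backbone$chromosomes[[cn]]
    clen <- nchar(cs)
    csites <- Filter(function(s) s$chrom == cn, sites)
    csites <- csites[order(vapply(csites, `[[`, numeric(1), "ref_start"))]
    # backbone segments between sites, plus a ref node per site
    walk_backbone <- list()  # per genome fragments
    per_genome <- setNames(rep(list(integer()), length(genome_ids)),
                           genome_ids)
    pos <- 0
    for (s in csites) {
      if (s$ref_start > pos) {
        seg <- new_node(subseq0(cs, pos, s$ref_start), cn, pos,
                        s$ref_start, backbone$genome_id)
        for (g in genome_ids) per_genome[[g]] <- c(per_genome[[g]], seg)
      }
      ref_seq <- subseq0(cs, s$ref_start, s$ref_end)
      ref_node <- if (nchar(ref_seq) > 0)
        new_node(ref_seq, cn, s$ref_start, s$ref_end, backbone$genome_id)
      else NA_integer_
      # distinct alternative alleles by sequence
      al_seq <- vapply(s$alleles, `[[`, character(1), "seq")
      al_gen <- vapply(s$alleles, `[[`, character(1), "genome")
      alt_seqs <- unique(al_seq)
      alt_nodes <- vapply(seq_along(alt_seqs), function(ai) {
        if (nchar(alt_seqs[ai]) == 0) return(NA_integer_)
        new_node(alt_seqs[ai], cn, NA, NA,
                 al_gen[match(alt_seqs[ai], al_seq)])
      }, integer(1))
      allele_of <- setNames(al_seq, al_gen)
      for (g in genome_ids) {
        node <- if (g %in% al_gen)
          alt_nodes[match(allele_of[[g]], alt_seqs)]
        else ref_node
        if (!is.na(node))
          per_genome[[g]] <- c(per_genome[[g]], node)
      }
      site_tab[[length(site_tab) + 1]] <- list(
        chrom = cn, ref_start = s$ref_start, ref_end = s$ref_end,
        ref_node = ref_node, ref_seq = ref_seq,
        alt_seqs = alt_seqs, alt_nodes = unname(alt_nodes),
        carriers = allele_of)
      pos <- s$ref_end
    }
    if (pos < clen) {
      seg <- new_node(subseq0(cs, pos, clen), cn, pos, clen,
                      backbone$genome_id)
      for (g in genome_ids) per_genome[[g]] <- c(per_genome[[g]], seg)
    }
    for (g in genome_ids) paths[[g]][[cn]] <- per_genome[[g]]
  }

  edges <- unique(do.call(rbind, lapply(paths, function(p)
    do.call(rbind, lapply(p, function(walk) {
      if (length(walk) < 2) return(NULL)
      data.frame(from = walk[-length(walk)], to = walk[-1])
    })))))
  if (is.null(edges)) edges <- data.frame(from = integer(), to = integer())
  rownames(edges) <- NULL
  structure(list(backbone = backbone$genome_id, nodes = nodes,
                 edges = edges, paths = paths, sites = site_tab,
                 genomes = genome_ids),
            class = "pan_graph")
}

#' @export
print.pan_graph <- function(x, ...) {
  cat(sprintf(paste0("<pan_graph> backbone %s: %d nodes, %d edges, ",
                     "%d genomes, %d variant sites\n"),
              x$backbone, nrow(x$nodes), nrow(x$edges),
              length(x$genomes), length(x$sites)))
  invisible(x)
}

#' Reconstruct a genome path's sequence from the graph
#'
#' @param graph a `pan_graph`.
#' @param genome_id genome whose path to concatenate.
#' @param chrom chromosome name.
#' @return concatenated node sequence of the walk.
#' @export
path_sequence <- function(graph, genome_id, chrom) {
  walk <- graph$paths[[genome_id]][[chrom]]
  paste(graph$nodes$seq[match(walk, graph$nodes$node_id)], collapse = "")
}

#' Pop bubbles from a pangenome graph
#'
#' Every site where at least two distinct internal paths connect a
#' backbone source to a backbone sink is reported once. Two paths make a
#' biallelic bubble, subtyped Ins (empty backbone allele), Del (empty
#' alternative) or Div (both non-empty); more than two paths make a
#' multiallelic bubble.
#'
#' @param graph a `pan_graph` from [build_graph()].
#' @return data.frame with one row per bubble: `chrom`, `ref_start`,
#'   `ref_end`, `n_paths`, `sv_type` (Ins/Del/Div/Multi), `ref_len`,
#'   `alt_len` (longest alternative), `alt_seqs` (comma-separated),
#'   `carriers` (comma-separated genome:allele pairs), `site_id`.
#' @export
pop_bubbles <- function(graph) {
  rows <- lapply(seq_along(graph$sites), function(i) {
    s <- graph$sites[[i]]
    # internal paths: the backbone allele plus each distinct alternative
    n_paths <- 1L + length(s$alt_seqs)
    if (n_paths < 2) return(NULL)
    sv_type <- if (n_paths > 2) "Multi" else {
      if (nchar(s$ref_seq) == 0) "Ins"
      else if (nchar(s$alt_seqs[1]) == 0) "Del"
      else "Div"
    }
    data.frame(site_id = sprintf("bub%05d", i), chrom = s$chrom,
               ref_start = s$ref_start, ref_end = s$ref_end,
               n_paths = n_paths, sv_type = sv_type,
               ref_len = nchar(s$ref_seq),
               alt_len = max(nchar(s$alt_seqs)),
               alt_seqs = paste(s$alt_seqs, collapse = ","),
               carriers = paste(names(s$carriers),
                                match(s$carriers, s$alt_seqs),
                                sep = ":", collapse = ","))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(site_id = character(), chrom = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      n_paths = integer(), sv_type = character(),
                      ref_len = numeric(), alt_len = numeric(),
                      alt_seqs = character(), carriers = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition graph nodes into core and variable classes
#'
#' A node is core when every genome's path traverses it, variable
#' otherwise; summary lengths and counts conserve the totals.
#'
#' @param graph a `pan_graph`.
#' @return list with `core_len`, `variable_len`, `core_count`,
#'   `variable_count`, and the per-node logical vector `is_core`.
#' @export
node_classes <- function(graph) {
  traversed <- lapply(graph$paths, function(p) unique(unlist(p)))
  is_core <- vapply(graph$nodes$node_id, function(id)
    all(vapply(traversed, function(tv) id %in% tv, logical(1))),
    logical(1))
  lens <- nchar(graph$nodes$seq)
  list(core_len = sum(lens[is_core]), variable_len = sum(lens[!is_core]),
       core_count = sum(is_core), variable_count = sum(!is_core),
       is_core = is_core)
}

#' Write a pangenome graph as GFA 1.0 with rGFA-like stable tags
#'
#' Segments carry SN (stable chromosome), SO (stable offset) and SR (rank:
#' 0 for backbone nodes, 1 for alternative alleles) tags; genome walks are
#' emitted as P lines.
#'
#' @param graph a `pan_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  nd <- graph$nodes
  sr <- ifelse(is.na(nd$start), 1L, 0L)
  so <- ifelse(is.na(nd$start), 0, nd$start)
  writeLines(sprintf("S\ts%d\t%s\tSN:Z:%s\tSO:i:%d\tSR:i:%d",
                     nd$node_id, nd$seq, nd$chrom, as.integer(so), sr),
             con)
  if (nrow(graph$edges) > 0)
    writeLines(sprintf("L\ts%d\t+\ts%d\t+\t0M", graph$edges$from,
                       graph$edges$to), con)
  for (g in names(graph$paths)) {
    for (cn in names(graph$paths[[g]])) {
      walk <- graph$paths[[g]][[cn]]
      if (length(walk) == 0) next
      writeLines(sprintf("P\t%s#%s\t%s\t*", g, cn,
                         paste0("s", walk, "+", collapse = ",")), con)
    }
  }
  invisible(path)
}

#' Write bubbles as VCF 4.2
#'
#' Alleles longer than `max_seq_len` are emitted symbolically
#' (`<INS>`/`<DEL>`/`<DIV>`) with END/SVLEN INFO fields; shorter alleles
#' are written with full sequences, left-padded with the preceding
#' backbone base in the usual VCF convention.
#'
#' @param bubbles data.frame from [pop_bubbles()].
#' @param backbone the backbone [annotated_genome()].
#' @param path output file path.
#' @param max_seq_len longest allele written out in full, bp.
#' @return `path`, invisibly.
#' @export
write_bubble_vcf <- function(bubbles, backbone, path, max_seq_len = 1000) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of reference span\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               sprintf("##contig=<ID=%s,length=%d>",
                       names(backbone$chromosomes),
                       nchar(backbone$chromosomes)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(bubbles) > 0) {
    for (i in seq_len(nrow(bubbles))) {
      b <- bubbles[i, ]
      cs <- backbone$chromosomes[[b$chrom]]
      pad <- subseq0(cs, b$ref_start - 1, b$ref_start)
      ref_seq <- subseq0(cs, b$ref_start, b$ref_end)
      alts <- strsplit(b$alt_seqs, ",", fixed = TRUE)[[1]]
      alts[alts == ""] <- ""
      len <- max(b$ref_len, b$alt_len)
      if (len > max_seq_len) {
        alt_field <- paste0("<", toupper(b$sv_type), ">")
        ref_field <- pad
      } else {
        ref_field <- paste0(pad, ref_seq)
        alt_field <- paste(paste0(pad, alts), collapse = ",")
      }
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s", b$chrom,
                         as.integer(b$ref_start), b$site_id, ref_field,
                         alt_field,
                         sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                                 toupper(b$sv_type),
                                 as.integer(b$ref_end), as.integer(len))),
                 con)
    }
  }
  invisible(path)
}
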