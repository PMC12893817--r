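#' Find exact-match anchors between two sequences
#'
#' Maximal exact matches seeded by shared k-mers, on both strands. In
#' `"mum"` mode (default) only matches seeded by a k-mer that is unique in
#' the reference are reported, suppressing repeat noise; `"mem"` mode
#' allows repeated seeds (up to an internal multiplicity cap).
#'
#' @param ref,qry DNA sequences (single character strings).
#' @param k seed k-mer size (>= 8; smaller seeds are refused as a
#'   spurious-match guard).
#' @param min_anchor_len minimum reported match length, bp.
#' @param mode `"mum"` or `"mem"`.
#' @return data.frame with columns `ref_start`, `qry_start` (0-based,
#'   forward-strand leftmost coordinates), `length`, `orientation`
#'   (`"+"`/`"-"`), with attributes `ref_len` and `qry_len`.
#' @export
find_anchors <- function(ref, qry, k = 19, min_anchor_len = 50,
                         mode = c("mum", "mem")) {
  mode <- match.arg(mode)
  if (k < 8) stop("k < 8 refused: seeds that short are spurious")
  if (k > min_anchor_len) stop("k must not exceed min_anchor_len")
  if (nchar(ref) == 0 || nchar(qry) == 0) stop("sequences must be non-empty")
  unique_ref <- mode == "mum"
  max_hits <- if (unique_ref) 1L else 16L
  fwd <- .find_anchors_fwd_cpp(ref, qry, k, min_anchor_len, unique_ref,
                               max_hits)
  qrc <- .revcomp_cpp(qry)
  rev <- .find_anchors_fwd_cpp(ref, qrc, k, min_anchor_len, unique_ref,
                               max_hits)
  nq <- nchar(qry)
  out <- rbind(
    if (nrow(fwd) > 0) data.frame(ref_start = fwd$ref_start,
                                  qry_start = fwd$qry_start,
                                  length = fwd$length, orientation = "+")
    else NULL,
    if (nrow(rev) > 0) data.frame(ref_start = rev$ref_start,
                                  qry_start = nq - (rev$qry_start +
                                                    rev$length),
                                  length = rev$length, orientation = "-")
    else NULL)
  if (is.null(out))
    out <- data.frame(ref_start = numeric(), qry_start = numeric(),
                      length = numeric(), orientation = character())
  out <- out[order(out$ref_start, out$qry_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_len") <- nchar(ref)
  attr(out, "qry_len") <- nq
  out
}

#' Chain collinear anchors with MUMmer-style parameters
#'
#' Anchors from one `(ref, qry, orientation)` stratum are linked into
#' collinear chains: two consecutive anchors may be joined when their gap
#' on both sequences is at most `max_gap` and their diagonals differ by at
#' most `diag_diff`. Chains whose summed anchor length falls below
#' `min_cluster` are discarded; chains overlapping a higher-scoring chain
#' on the query are dropped.
#'
#' @param anchors data.frame from [find_anchors()] (one orientation).
#' @param max_gap maximum inter-anchor gap, bp.
#' @param min_cluster minimum summed anchor length of a chain, bp.
#' @param diag_diff maximum diagonal difference between joined anchors, bp.
#' @param qry_len query sequence length (taken from the `qry_len`
#'   attribute of `anchors` when missing); required for minus-strand
#'   chaining.
#' @return list of chains; each chain is a list with `anchors` (the member
#'   rows), `ref_start`, `ref_end`, `qry_start`, `qry_end` (forward
#'   strand), `orientation` and `score` (summed anchor length).
#' @export
chain_anchors <- function(anchors, max_gap = 500, min_cluster = 1000,
                          diag_diff = 20, qry_len = NULL) {
  qry_len <- qry_len %||% attr(anchors, "qry_len")
  if (nrow(anchors) == 0) return(list())
  ori <- unique(anchors$orientation)
  if (length(ori) != 1)
    stop("chain_anchors expects anchors from a single orientation stratum")
  if (ori == "-" && is.null(qry_len))
    stop("qry_len required for minus-strand chaining")
  # work in a space where collinear means increasing in both coordinates
  q <- if (ori == "+") anchors$qry_start
       else qry_len - (anchors$qry_start + anchors$length)
  r <- anchors$ref_start
  l <- anchors$length
  n <- length(r)
  ord <- order(r, q)
  r <- r[ord]; q <- q[ord]; l <- l[ord]
  diag <- r - q

  # DP restricted to near-identical diagonals (|ddiag| <= diag_diff)
  band <- floor(diag / max(diag_diff, 1))
  by_band <- split(seq_len(n), band)
  score <- l
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- unlist(by_band[as.character((band[i] - 1):(band[i] + 1))],
                   use.names = FALSE)
    cand <- cand[cand < i]
    for (j in cand) {
      if (abs(diag[i] - diag[j]) > diag_diff) next
      rgap <- r[i] - (r[j] + l[j])
      qgap <- q[i] - (q[j] + l[j])
      if (rgap > max_gap || qgap > max_gap) next
      if (rgap < -diag_diff || qgap < -diag_diff) next
      s <- score[j] + l[i] - max(rgap, qgap, 0) / 100
      if (s > score[i]) { score[i] <- s; pred[i] <- j }
    }
  }
  used <- rep(FALSE, n)
  chains <- list()
  for (e in order(score, decreasing = TRUE)) {
    if (used[e]) next
    path <- integer()
    i <- e
    while (!is.na(i) && !used[i]) {
      path <- c(i, path)
      used[i] <- TRUE
      i <- pred[i]
    }
    mem <- data.frame(ref_start = r[path], qry_start = q[path],
                      length = l[path])
    tot <- sum(mem$length)
    if (tot < min_cluster) next
    qs <- min(mem$qry_start); qe <- max(mem$qry_start + mem$length)
    if (ori == "-") { tmp <- qs; qs <- qry_len - qe; qe <- qry_len - tmp }
    chains[[length(chains) + 1]] <- structure(list(
      anchors = mem,  # chaining-space coordinates
      ref_start = min(mem$ref_start),
      ref_end = max(mem$ref_start + mem$length),
      qry_start = qs, qry_end = qe,
      orientation = ori, score = tot, qry_len = qry_len),
      class = "anchor_chain")
  }
  # best-score wins on query overlap
  drop_query_overlaps(chains)
}

# best-score-wins overlap resolution on the query; overlaps up to `tol` bp
# are tolerated because maximal matches extend into breakpoint
# micro-homology, making adjacent chains abut with small overlaps
drop_query_overlaps <- function(chains, tol = 100) {
  if (length(chains) <= 1) return(chains)
  ord <- order(vapply(chains, `[[`, numeric(1), "score"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    ch <- chains[[i]]
    clash <- any(vapply(kept, function(kc) {
      if ((kc$qry_chrom %||% "") != (ch$qry_chrom %||% "")) return(FALSE)
      ov <- min(kc$qry_end, ch$qry_end) - max(kc$qry_start, ch$qry_start)
      ov > tol
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1]] <- ch
  }
  kept[order(vapply(kept, `[[`, numeric(1), "ref_start"))]
}

#' Classify within-chain gaps into raw variants
#'
#' Each gap between consecutive anchors of a chain is classified by its
#' reference gap `r` and query gap `q`: `r = 0, q > 0` is an insertion of
#' length `q`; `r > 0, q = 0` a deletion of length `r`; both positive a
#' divergent allele of length `max(r, q)`. Only variants of length at
#' least `min_sv` are emitted; the alternative sequence is captured
#' verbatim from the query (reference-oriented).
#'
#' @param chain an `anchor_chain` from [chain_anchors()].
#' @param ref,qry the sequences the chain was built from.
#' @param min_sv minimum emitted variant length, bp.
#' @return data.frame of raw variants (`type`, `ref_start`, `ref_end`,
#'   `qry_start`, `qry_end`, `length`, `seq`); query coordinates are
#'   forward strand.
#' @export
gap_variants <- function(chain, ref, qry, min_sv = 50) {
  mem <- chain$anchors
  out <- empty_raw_variants()
  if (nrow(mem) < 2) return(out)
  neg <- chain$orientation == "-"
  qseq <- if (neg) .revcomp_cpp(qry) else qry
  nq <- nchar(qry)
  for (i in 2:nrow(mem)) {
    r0 <- mem$ref_start[i - 1] + mem$length[i - 1]
    r1 <- mem$ref_start[i]
    q0 <- mem$qry_start[i - 1] + mem$length[i - 1]
    q1 <- mem$qry_start[i]
    rgap <- r1 - r0; qgap <- q1 - q0
    if (r0 < 0 || r1 > nchar(ref) || q0 < 0 || q1 > nchar(qseq))
      stop("gap coordinates outside sequences: internal inconsistency")
    # trim breakpoint micro-homology off the left anchor so the emitted
    # interval stays junction-consistent
    t <- max(0, -rgap, -qgap)
    r0 <- r0 - t; q0 <- q0 - t
    rgap <- r1 - r0; qgap <- q1 - q0
    if (rgap < 0 || qgap < 0) next
    v <- classify_gap(rgap, qgap)
    if (is.na(v$type) || v$length < min_sv) next
    seq <- if (qgap > 0) subseq0(qseq, q0, q1) else ""
    qs <- q0; qe <- q1
    if (neg) { qs <- nq - q1; qe <- nq - q0 }
    out <- rbind(out, data.frame(
      type = v$type, ref_start = r0, ref_end = r1,
      qry_start = qs, qry_end = qe, length = v$length, seq = seq))
  }
  out
}

classify_gap <- function(rgap, qgap) {
  if (qgap > 0 && rgap == 0) list(type = "INS", length = qgap)
  else if (rgap > 0 && qgap == 0) list(type = "DEL", length = rgap)
  else if (rgap > 0 && qgap > 0) list(type = "DIV",
                                      length = max(rgap, qgap))
  else list(type = NA_character_, length = 0)
}

empty_raw_variants <- function() {
  data.frame(type = character(), ref_start = numeric(),
             ref_end = numeric(), qry_start = numeric(),
             qry_end = numeric(), length = numeric(), seq = character())
}

#' Detect inversions, translocations and tandem duplications from chains
#'
#' Operates on all chains of one genome pair (all chromosome pairs, both
#' orientations, with chromosome fields attached as produced by
#' [genome_pair_variants()]'s internals). A minus-orientation chain
#' embedded in plus context is an inversion over its reference interval; a
#' chain whose query maps to a different chromosome (or far off the
#' collinear backbone of its own chromosome) is a translocation reported
#' as a breakend pair; two query-adjacent chains overlapping on the
#' reference are a tandem duplication.
#'
#' @param chains list of `anchor_chain` objects carrying `ref_chrom` and
#'   `qry_chrom` fields.
#' @param min_sv minimum reported length, bp.
#' @param dup_max_qry_gap maximum query gap between the two chains of a
#'   tandem duplication, bp.
#' @return data.frame with columns `type` (`INV`/`TRA`/`DUP`), `ref_chrom`,
#'   `ref_start`, `ref_end`, `length`, `qry_chrom`, `qry_start`, `qry_end`,
#'   `dest_chrom`, `dest_pos` (TRA acceptor locus in reference
#'   coordinates).
#' @export
detect_rearrangements <- function(chains, min_sv = 50,
                                  dup_max_qry_gap = 100) {
  out <- data.frame(type = character(), ref_chrom = character(),
                    ref_start = numeric(), ref_end = numeric(),
                    length = numeric(), qry_chrom = character(),
                    qry_start = numeric(), qry_end = numeric(),
                    dest_chrom = character(), dest_pos = numeric())
  if (length(chains) == 0) return(out)
  rc <- vapply(chains, function(c) c$ref_chrom %||% "ref", character(1))
  qc <- vapply(chains, function(c) c$qry_chrom %||% "qry", character(1))
  ori <- vapply(chains, `[[`, character(1), "orientation")

  # dominant reference chromosome for each query chromosome (by aligned bp)
  dom <- tapply(vapply(chains, `[[`, numeric(1), "score"),
                list(qc, rc), sum)
  dom_ref <- apply(dom, 1, function(x) colnames(dom)[which.max(x)])

  # collinear backbone per query chromosome: heaviest increasing subset of
  # plus chains on the dominant reference chromosome
  backbone_idx <- integer()
  for (q in unique(qc)) {
    idx <- which(qc == q & rc == dom_ref[[q]] & ori == "+")
    backbone_idx <- c(backbone_idx, lis_chains(chains, idx))
  }

  add <- function(type, ch, len, ref_start, ref_end, dest_chrom = NA,
                  dest_pos = NA) {
    out <<- rbind(out, data.frame(
      type = type, ref_chrom = ch$ref_chrom %||% "ref",
      ref_start = ref_start, ref_end = ref_end, length = len,
      qry_chrom = ch$qry_chrom %||% "qry",
      qry_start = ch$qry_start, qry_end = ch$qry_end,
      dest_chrom = dest_chrom, dest_pos = dest_pos))
  }

  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    len <- ch$ref_end - ch$ref_start
    if (ori[i] == "-") {
      if (len >= min_sv) add("INV", ch, len, ch$ref_start, ch$ref_end)
      next
    }
    displaced <- rc[i] != dom_ref[[qc[i]]] ||
      (!(i %in% backbone_idx) && min_chain_displacement(chains, i,
                                                        backbone_idx,
                                                        qc, rc) > 10000)
    if (displaced && len >= min_sv) {
      acc <- map_via_backbone(chains, backbone_idx, qc, ch$qry_chrom,
                              ch$qry_start)
      add("TRA", ch, len, ch$ref_start, ch$ref_end,
          dest_chrom = acc$chrom, dest_pos = acc$pos)
    }
  }

  # tandem duplications: query-adjacent chains overlapping on reference
  for (q in unique(qc)) {
    idx <- which(qc == q & ori == "+")
    idx <- idx[order(vapply(chains[idx], `[[`, numeric(1), "qry_start"))]
    if (length(idx) < 2) next
    for (j in 2:length(idx)) {
      a <- chains[[idx[j - 1]]]; b <- chains[[idx[j]]]
      if ((a$ref_chrom %||% "") != (b$ref_chrom %||% "")) next
      qgap <- b$qry_start - a$qry_end
      overlap <- a$ref_end - b$ref_start
      if (qgap <= dup_max_qry_gap && overlap >= min_sv) {
        add("DUP", b, overlap, b$ref_start, a$ref_end)
      }
    }
  }
  out
}

# heaviest strictly-increasing (ref_start vs qry order) subset of chains
lis_chains <- function(chains, idx) {
  if (length(idx) == 0) return(integer())
  qs <- vapply(chains[idx], `[[`, numeric(1), "qry_start")
  rs <- vapply(chains[idx], `[[`, numeric(1), "ref_start")
  sc <- vapply(chains[idx], `[[`, numeric(1), "score")
  ord <- order(qs)
  m <- length(ord)
  best <- sc[ord]; pred <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (rs[ord[j]] < rs[ord[i]] && best[j] + sc[ord[i]] > best[i]) {
        best[i] <- best[j] + sc[ord[i]]; pred[i] <- j
      }
    }
  }
  i <- which.max(best)
  keep <- integer()
  while (!is.na(i)) { keep <- c(keep, ord[i]); i <- pred[i] }
  idx[keep]
}

# displacement of chain i from where the backbone maps its query interval
min_chain_displacement <- function(chains, i, backbone_idx, qc, rc) {
  ch <- chains[[i]]
  acc <- map_via_backbone(chains, backbone_idx, qc, ch$qry_chrom,
                          ch$qry_start)
  if (is.na(acc$pos)) return(Inf)
  if (!identical(acc$chrom, ch$ref_chrom %||% "ref")) return(Inf)
  abs(acc$pos - ch$ref_start)
}

# map a query-chromosome position into reference coordinates via the
# nearest collinear backbone chain
map_via_backbone <- function(chains, backbone_idx, qc, qchrom, qpos) {
  idx <- backbone_idx[qc[backbone_idx] == qchrom]
  if (length(idx) == 0) return(list(chrom = NA_character_, pos = NA_real_))
  qs <- vapply(chains[idx], `[[`, numeric(1), "qry_start")
  best <- idx[which.min(abs(qs - qpos))]
  ch <- chains[[best]]
  list(chrom = ch$ref_chrom %||% "ref",
       pos = ch$ref_start + (qpos - ch$qry_start))
}

#' Call all raw variants between two annotated genomes
#'
#' Full pairwise pipeline: anchors on every chromosome pair and both
#' strands, MUMmer-parameter chaining, rearrangement detection
#' (INV/TRA/DUP), and gap classification both within chains and between
#' consecutive collinear chains (the equivalent of between-alignment
#' variants). Gaps explained by a detected rearrangement are suppressed so
#' a translocation is not double-reported as a deletion plus insertion.
#'
#' @param ref_genome,qry_genome [annotated_genome()] objects.
#' @param k seed k-mer size.
#' @param min_anchor_len minimum anchor length, bp.
#' @param max_gap,min_cluster,diag_diff chaining parameters
#'   (see [chain_anchors()]).
#' @param min_sv minimum emitted variant length, bp.
#' @param mode anchor mode, see [find_anchors()].
#' @return data.frame of raw variants: `type` in INS/DEL/DIV/INV/DUP/TRA,
#'   `ref_chrom`, `ref_start`, `ref_end`, `qry_chrom`, `qry_start`,
#'   `qry_end`, `length`, `seq`, `dest_chrom`, `dest_pos`.
#' @export
genome_pair_variants <- function(ref_genome, qry_genome, k = 19,
                                 min_anchor_len = 50, max_gap = 500,
                                 min_cluster = 1000, diag_diff = 20,
                                 min_sv = 50, mode = "mum") {
  chains <- list()
  for (rc in names(ref_genome$chromosomes)) {
    rs <- ref_genome$chromosomes[[rc]]
    for (qc in names(qry_genome$chromosomes)) {
      qs <- qry_genome$chromosomes[[qc]]
      anc <- find_anchors(rs, qs, k = k, min_anchor_len = min_anchor_len,
                          mode = mode)
      for (o in c("+", "-")) {
        sub <- anc[anc$orientation == o, , drop = FALSE]
        if (nrow(sub) == 0) next
        cs <- chain_anchors(sub, max_gap = max_gap,
                            min_cluster = min_cluster,
                            diag_diff = diag_diff, qry_len = nchar(qs))
        for (ch in cs) {
          ch$ref_chrom <- rc; ch$qry_chrom <- qc
          chains[[length(chains) + 1]] <- ch
        }
      }
    }
  }
  chains <- drop_query_overlaps(chains)
  rearr <- detect_rearrangements(chains, min_sv = min_sv)

  out <- empty_pair_variants()
  if (nrow(rearr) > 0) {
    out <- rbind(out, data.frame(
      type = rearr$type, ref_chrom = rearr$ref_chrom,
      ref_start = rearr$ref_start, ref_end = rearr$ref_end,
      qry_chrom = rearr$qry_chrom, qry_start = rearr$qry_start,
      qry_end = rearr$qry_end, length = rearr$length, seq = "",
      dest_chrom = rearr$dest_chrom, dest_pos = rearr$dest_pos))
  }

  rcv <- vapply(chains, function(c) c$ref_chrom, character(1))
  qcv <- vapply(chains, function(c) c$qry_chrom, character(1))
  oriv <- vapply(chains, `[[`, character(1), "orientation")
  tra_q <- rearr[rearr$type == "TRA", , drop = FALSE]
  inv_r <- rearr[rearr$type == "INV", , drop = FALSE]
  tra_r <- tra_q

  for (qc in unique(qcv)) {
    # dominant reference chromosome for this query chromosome
    cand <- which(qcv == qc & oriv == "+")
    if (length(cand) == 0) next
    sc <- vapply(chains[cand], `[[`, numeric(1), "score")
    rc <- names(which.max(tapply(sc, rcv[cand], sum)))
    idx <- cand[rcv[cand] == rc]
    # restrict to the collinear backbone of this query chromosome
    idx <- lis_chains(chains, idx)
    if (length(idx) == 0) next
    idx <- idx[order(vapply(chains[idx], `[[`, numeric(1), "ref_start"))]
    rs <- ref_genome$chromosomes[[rc]]
    qs <- qry_genome$chromosomes[[qc]]
    # within-chain gaps
    for (i in idx) {
      gv <- gap_variants(chains[[i]], rs, qs, min_sv = min_sv)
      if (nrow(gv) > 0) {
        out <- rbind(out, data.frame(
          type = gv$type, ref_chrom = rc, ref_start = gv$ref_start,
          ref_end = gv$ref_end, qry_chrom = qc, qry_start = gv$qry_start,
          qry_end = gv$qry_end, length = gv$length, seq = gv$seq,
          dest_chrom = NA_character_, dest_pos = NA_real_))
      }
    }
    # between-chain gaps
    if (length(idx) < 2) next
    for (j in 2:length(idx)) {
      a <- chains[[idx[j - 1]]]; b <- chains[[idx[j]]]
      rgap <- b$ref_start - a$ref_end
      qgap <- b$qry_start - a$qry_end
      if (rgap < -100 || qgap < -100) next
      # trim breakpoint micro-homology off the left chain so the emitted
      # interval stays junction-consistent
      t <- max(0, -rgap, -qgap)
      r0 <- a$ref_end - t; q0 <- a$qry_end - t
      rgap <- b$ref_start - r0; qgap <- b$qry_start - q0
      v <- classify_gap(rgap, qgap)
      if (is.na(v$type) || v$length < min_sv) next
      # suppress gaps explained by a rearrangement
      if (nrow(inv_r) > 0 &&
          any(inv_r$ref_chrom == rc & inv_r$ref_start < b$ref_start &
              inv_r$ref_end > a$ref_end)) next
      if (nrow(tra_r) > 0 && v$type != "INS" &&
          any(tra_r$ref_chrom == rc & tra_r$ref_start < b$ref_start &
              tra_r$ref_end > a$ref_end)) next
      if (nrow(tra_q) > 0 && v$type != "DEL" &&
          any(tra_q$qry_chrom == qc & tra_q$qry_start < b$qry_start &
              tra_q$qry_end > a$qry_end)) next
      seq <- if (qgap > 0) subseq0(qs, q0, q0 + qgap) else ""
      out <- rbind(out, data.frame(
        type = v$type, ref_chrom = rc, ref_start = r0,
        ref_end = r0 + rgap, qry_chrom = qc, qry_start = q0,
        qry_end = q0 + qgap, length = v$length, seq = seq,
        dest_chrom = NA_character_, dest_pos = NA_real_))
    }
  }
  rownames(out) <- NULL
  out
}

empty_pair_variants <- function() {
  data.frame(type = character(), ref_chrom = character(),
             ref_start = numeric(), ref_end = numeric(),
             qry_chrom = character(), qry_start = numeric(),
             qry_end = numeric(), length = numeric(), seq = character(),
             dest_chrom = character(), dest_pos = numeric())
}
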