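# standard genetic code used for NG86 site and pathway counting
.codon_aa <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      b <- c("T", "C", "A", "G")
      codons <- as.vector(outer(outer(b, b, function(x, y) paste0(x, y)),
                                b, paste0))
      # standard genetic code in TCAG order
      aa <- strsplit(paste0(
        "FFLLSSSSYY**CC*W",
        "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR",
        "VVVVAAAADDEEGGGG"), "")[[1]]
      ord <- as.vector(vapply(b, function(p1)
        vapply(b, function(p2) paste0(p1, p2, b), character(4)),
        matrix("", 4, 4)))
      tab <<- setNames(aa, ord)
    }
    tab
  }
})

translate_codon <- function(codon) unname(.codon_aa()[codon])

# fraction of synonymous sites per codon (changes to stop codons count as
# nonsynonymous)
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  if (is.na(aa) || aa == "*") return(NA_real_)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(bases, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (identical(translate_codon(mut), aa)) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways through stop codons are excluded
codon_differences <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(pos) else {
    if (nd == 2) lapply(list(c(1, 2), c(2, 1)), function(o) pos[o])
    else lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                     c(3, 1, 2), c(3, 2, 1)), function(o) pos[o])
  }
  sds <- numeric(); nds <- numeric()
  for (p in perms) {
    cur <- c1
    sd <- 0; ndd <- 0; valid <- TRUE
    for (step in p) {
      nxt <- cur
      substr(nxt, step, step) <- substr(c2, step, step)
      a1 <- translate_codon(cur); a2 <- translate_codon(nxt)
      if (a2 == "*" && nxt != c2) { valid <- FALSE; break }
      if (a1 == a2) sd <- sd + 1 else ndd <- ndd + 1
      cur <- nxt
    }
    if (valid) { sds <- c(sds, sd); nds <- c(nds, ndd) }
  }
  if (length(sds) == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = mean(sds), nd = mean(nds))
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Synonymous and nonsynonymous site counts are averaged over both
#' sequences; codons differing at several positions average their
#' synonymous/nonsynonymous differences over all minimal mutational
#' pathways (pathways through stop codons excluded); proportions are
#' corrected with the Jukes-Cantor formula. Codons containing gaps
#' (`-`) or ambiguous bases are skipped.
#'
#' @param cds_a,cds_b aligned coding sequences of equal length divisible
#'   by three, without internal stop codons.
#' @return list with `Ka`, `Ks`, `ratio` (NA when Ks is 0), `pN`, `pS`,
#'   `N`, `S`, and logical `saturated` (TRUE when a proportion reached
#'   the 3/4 ceiling so the correction is undefined; the corresponding
#'   rate is NA, not fabricated).
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned CDS must have equal length")
  if (nchar(cds_a) %% 3 != 0) stop("CDS length must be divisible by 3")
  n_codon <- nchar(cds_a) / 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n_codon)) {
    c1 <- substr(cds_a, 3 * i - 2, 3 * i)
    c2 <- substr(cds_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    a1 <- translate_codon(c1); a2 <- translate_codon(c2)
    if (a1 == "*" || a2 == "*") {
      if (i == n_codon) next  # terminal stop codon: not a coding site
      stop("internal stop codon at codon ", i)
    }
    s1 <- codon_syn_sites(c1); s2 <- codon_syn_sites(c2)
    S <- S + (s1 + s2) / 2
    N <- N + 3 - (s1 + s2) / 2
    d <- codon_differences(c1, c2)
    if (anyNA(d)) next
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (S == 0 && N == 0) stop("no comparable codons")
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (pS >= 3 / 4) || (pN >= 3 / 4)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(Ka = Ka, Ks = Ks, ratio = ratio, pN = pN, pS = pS, N = N, S = S,
       saturated = saturated)
}
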