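#' Annotated genome container
#'
#' Bundles chromosome sequences with gene models. Coordinates are 0-based
#' half-open internally; GFF3 emission converts to 1-based closed intervals.
#' In this package every exon is coding (exon == CDS), so the concatenated
#' exon sequence of a gene is its CDS.
#'
#' @param genome_id single string naming the genome/accession.
#' @param chromosomes named character vector of chromosome sequences.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (gene span, 0-based half-open) and a
#'   list-column `exons` of two-column integer matrices (`start`, `end`,
#'   0-based half-open, sorted, non-overlapping).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, chromosomes, genes = empty_genes()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1,
            is.character(chromosomes), !is.null(names(chromosomes)))
  if (anyDuplicated(names(chromosomes)))
    stop("chromosome names must be unique")
  genes <- as.data.frame(genes)
  g <- structure(list(genome_id = genome_id,
                      chromosomes = chromosomes,
                      genes = genes),
                 class = "annotated_genome")
  validate_genome(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d chromosome(s), %s bp, %d gene(s)\n",
              x$genome_id, length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

empty_genes <- function() {
  data.frame(gene_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             exons = I(list()))
}

validate_genome <- function(g) {
  genes <- g$genes
  if (nrow(genes) == 0) return(invisible(g))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$chrom %in% names(g$chromosomes)))
    stop("gene placed on unknown chromosome")
  lens <- nchar(g$chromosomes)[genes$chrom]
  if (any(genes$start < 0) || any(genes$end > lens))
    stop("gene interval outside its chromosome")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) < 1 || any(ex[, 2] <= ex[, 1]))
      stop("empty or inverted exon in gene ", genes$gene_id[i])
    if (is.unsorted(ex[, 1], strictly = TRUE) ||
        any(ex[-1, 1] < ex[-nrow(ex), 2]))
      stop("exons overlap or are unsorted in gene ", genes$gene_id[i])
  }
  invisible(g)
}

#' Extract the CDS sequence of a gene
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand genes.
#'
#' @param genome an [annotated_genome()].
#' @param gene_id gene identifier.
#' @return CDS as a single character string.
#' @export
cds_sequence <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  gr <- genome$genes[i, ]
  chrom <- genome$chromosomes[[gr$chrom]]
  ex <- gr$exons[[1]]
  s <- paste(substring(chrom, ex[, 1] + 1, ex[, 2]), collapse = "")
  if (gr$strand == "-") s <- revcomp(s)
  s
}

#' All CDS sequences of a genome
#'
#' @param genome an [annotated_genome()].
#' @return named character vector of CDS sequences (names are gene ids).
#' @export
cds_sequences <- function(genome) {
  ids <- genome$genes$gene_id
  setNames(vapply(ids, function(id) cds_sequence(genome, id), character(1)),
           ids)
}

# gene order (rank) per chromosome, by start coordinate
gene_ranks <- function(genome) {
  genes <- genome$genes
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      rank = integer()))
  out <- do.call(rbind, lapply(split(genes, genes$chrom), function(df) {
    df <- df[order(df$start), ]
    data.frame(gene_id = df$gene_id, chrom = df$chrom,
               rank = seq_len(nrow(df)))
  }))
  rownames(out) <- NULL
  out
}

#' Write chromosome sequences as FASTA
#'
#' Sequences are wrapped at 60 columns; output is deterministic.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dna, path, width = 60)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with 1-based closed coordinates.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- genome$genes
  if (nrow(genes) > 0) {
    ord <- order(genes$chrom, genes$start)
    for (i in ord) {
      gr <- genes[i, ]
      gid <- gr$gene_id
      base <- sprintf("%s\tpansv\t%%s\t%%d\t%%d\t.\t%s\t%%s\t%%s",
                      gr$chrom, gr$strand)
      writeLines(sprintf(base, "gene", gr$start + 1, gr$end, ".",
                         sprintf("ID=%s", gid)), con)
      writeLines(sprintf(base, "mRNA", gr$start + 1, gr$end, ".",
                         sprintf("ID=%s.t1;Parent=%s", gid, gid)), con)
      ex <- gr$exons[[1]]
      # CDS phase: cumulative coding length before each exon, in
      # translation order (reversed for minus strand)
      n_ex <- nrow(ex)
      lens <- ex[, 2] - ex[, 1]
      tr_order <- if (gr$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      phase <- integer(n_ex)
      cum <- 0L
      for (j in tr_order) {
        phase[j] <- (3L - cum %% 3L) %% 3L
        cum <- cum + lens[j]
      }
      for (j in seq_len(n_ex)) {
        writeLines(sprintf(base, "exon", ex[j, 1] + 1, ex[j, 2], ".",
                           sprintf("ID=%s.t1.exon%d;Parent=%s.t1",
                                   gid, j, gid)), con)
        writeLines(sprintf(base, "CDS", ex[j, 1] + 1, ex[j, 2],
                           as.character(phase[j]),
                           sprintf("ID=%s.t1.cds;Parent=%s.t1", gid, gid)),
                   con)
      }
    }
  }
  invisible(path)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Expects gene/CDS features as written by [write_genes_gff3()]: CDS
#' features carry `Parent=<gene>.t1` attributes and define the exons.
#'
#' @param genome_id name for the genome.
#' @param fasta path to chromosome FASTA.
#' @param gff3 path to gene models in GFF3 (optional).
#' @return An [annotated_genome()].
#' @export
read_annotated_genome <- function(genome_id, fasta, gff3 = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  chroms <- setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
  genes <- empty_genes()
  if (!is.null(gff3)) {
    tab <- read.table(gff3, sep = "\t", quote = "", comment.char = "#",
                      col.names = c("chrom", "source", "type", "start",
                                    "end", "score", "strand", "phase",
                                    "attr"),
                      stringsAsFactors = FALSE)
    cds <- tab[tab$type == "CDS", ]
    gid <- sub("^.*Parent=([^;]+)\\.t1.*$", "\\1", cds$attr)
    parts <- split(cds, gid)
    genes <- do.call(rbind, lapply(names(parts), function(id) {
      df <- parts[[id]][order(parts[[id]]$start), ]
      ex <- cbind(start = df$start - 1L, end = df$end)
      data.frame(gene_id = id, chrom = df$chrom[1], strand = df$strand[1],
                 start = min(ex[, 1]), end = max(ex[, 2]),
                 exons = I(list(ex)))
    }))
  }
  annotated_genome(genome_id, chroms, genes)
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with columns `read_id` and `seq` as produced by
#'   [simulate_reads()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq),
                 function(n) paste(rep("I", n), collapse = ""), character(1))
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}
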