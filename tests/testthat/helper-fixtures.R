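# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small backbone + one derived accession with a mixed event set
fix_small_pair <- function() fixture("small_pair", function() {
  anc <- simulate_ancestor(2, 200000, 12, seed = 7)
  ev <- sample_sv_events(anc, 10,
                         types = c("INS", "DEL", "DIV", "INV", "TRA"),
                         max_len = 3000, seed = 3)
  d <- derive_accession(anc, ev, snp_rate = 0.001, seed = 11,
                        genome_id = "acc1")
  list(anc = anc, ev = ev, genome = d$genome, truth = d$truth)
})

# backbone + three derived genomes with INS/DEL/DIV only (graph fodder)
fix_graph_set <- function() fixture("graph_set", function() {
  anc <- simulate_ancestor(1, 250000, 8, seed = 5)
  derived <- list(); truths <- list()
  for (i in 1:3) {
    ev <- sample_sv_events(anc, 8, types = c("INS", "DEL", "DIV"),
                           max_len = 2000, seed = 100 + i)
    d <- derive_accession(anc, ev, snp_rate = 5e-4, seed = 200 + i,
                          genome_id = paste0("acc", i))
    derived[[i]] <- d$genome
    truths[[i]] <- d$truth
  }
  graph <- build_graph(anc, derived)
  list(anc = anc, derived = derived, truths = truths, graph = graph)
})

# match planted events against a called variant table (graph bubbles or
# raw pair variants); returns logical hit vector
events_recovered <- function(ev, calls, type_map, pos_tol = 10,
                             len_tol = 10) {
  vapply(seq_len(nrow(ev)), function(i) {
    ty <- type_map[[ev$type[i]]]
    any(calls$type %in% ty & calls$chrom == ev$chrom[i] &
          abs(calls$pos - ev$pos[i]) <= pos_tol &
          abs(calls$length - ev$length[i]) <= len_tol)
  }, logical(1))
}

# hand-built annotated genome: one gene, 2 exons on given strand
toy_gene_genome <- function(strand = "+", seed = 42) {
  with_seed_local(seed, {
    tpl <- pansv:::make_gene_template("gX", n_codons = 60, n_exons = 2)
    loc <- pansv:::orient_gene(tpl, strand)
    left <- random_dna(4000)
    right <- random_dna(4000)
    chrom <- paste0(left, loc$seq, right)
    genes <- data.frame(gene_id = "gX", chrom = "chr1", strand = strand,
                        start = 4000, end = 4000 + nchar(loc$seq),
                        exons = I(list(loc$exons + 4000)))
    annotated_genome("toy", c(chr1 = chrom), genes)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
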