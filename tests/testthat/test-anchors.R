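test_that("identical sequences give one full-length anchor", {
  s <- with_seed_local(1, random_dna(5000))
  a <- find_anchors(s, s, k = 15, min_anchor_len = 50)
  expect_equal(nrow(a), 1)
  expect_equal(a$ref_start, 0)
  expect_equal(a$qry_start, 0)
  expect_equal(a$length, 5000)
  expect_equal(a$orientation, "+")
})

test_that("a novel insertion splits the alignment into two anchors", {
  ref <- with_seed_local(2, random_dna(5000))
  ins <- with_seed_local(3, random_dna(100))
  # force mismatches at the insert boundaries so both anchors are exactly
  # 2500 bp (no micro-homology extension)
  pick_diff <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  substr(ins, 1, 1) <- pick_diff(substr(ref, 2501, 2501))
  substr(ins, 100, 100) <- pick_diff(substr(ref, 2500, 2500))
  qry <- paste0(substr(ref, 1, 2500), ins, substr(ref, 2501, 5000))
  a <- find_anchors(ref, qry, k = 15, min_anchor_len = 50)
  a <- a[a$orientation == "+", ]
  a <- a[order(a$ref_start), ]
  expect_equal(nrow(a), 2)
  expect_equal(a$ref_start, c(0, 2500))
  expect_equal(a$qry_start, c(0, 2600))
  expect_equal(a$length, c(2500, 2500))
})

test_that("sequences without shared k-mers yield no anchors, small k refused", {
  expect_equal(nrow(find_anchors(strrep("A", 1000), strrep("C", 1000),
                                 k = 15, min_anchor_len = 50)), 0)
  expect_error(find_anchors("ACGT", "ACGT", k = 7, min_anchor_len = 50),
               "k < 8")
})

test_that("anchors are symmetric under coordinate swap on repeat-free input", {
  for (seed in 1:3) {
    ref <- with_seed_local(seed, random_dna(4000))
    ev <- with_seed_local(seed + 10, {
      list(random_dna(200), sample(1000:3000, 1))
    })
    qry <- paste0(substr(ref, 1, ev[[2]]), ev[[1]],
                  substr(ref, ev[[2]] + 1, 4000))
    ab <- find_anchors(ref, qry, k = 15, min_anchor_len = 50)
    ba <- find_anchors(qry, ref, k = 15, min_anchor_len = 50)
    swapped <- data.frame(ref_start = ba$qry_start, qry_start = ba$ref_start,
                          length = ba$length, orientation = ba$orientation)
    swapped <- swapped[order(swapped$ref_start, swapped$qry_start), ]
    rownames(swapped) <- NULL
    expect_equal(ab[, names(swapped)], swapped)
  }
})

test_that("reverse-complement segments are found on the minus strand", {
  ref <- with_seed_local(5, random_dna(6000))
  qry <- paste0(substr(ref, 1, 2000),
                revcomp(substr(ref, 2001, 4000)),
                substr(ref, 4001, 6000))
  a <- find_anchors(ref, qry, k = 15, min_anchor_len = 50)
  neg <- a[a$orientation == "-", ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$ref_start, 2000)
  expect_equal(neg$qry_start, 2000)
  expect_equal(neg$length, 2000)
})

test_that("chaining follows maxgap/diagdiff semantics", {
  # a single long anchor forms one chain scoring its length
  one <- data.frame(ref_start = 0, qry_start = 0, length = 2000,
                    orientation = "+")
  cs <- chain_anchors(one, qry_len = 5000)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$score, 2000)

  # two collinear anchors separated by a 600 bp gap exceed maxgap 500:
  # two chains (here both survive min_cluster at 1000 bp each)
  two <- data.frame(ref_start = c(0, 1600), qry_start = c(0, 1600),
                    length = c(1000, 1000), orientation = "+")
  cs2 <- chain_anchors(two, max_gap = 500, min_cluster = 1000,
                       qry_len = 5000)
  expect_length(cs2, 2)
  # with a 400 bp gap they join into one chain
  two$ref_start[2] <- two$qry_start[2] <- 1400
  cs3 <- chain_anchors(two, max_gap = 500, min_cluster = 1000,
                       qry_len = 5000)
  expect_length(cs3, 1)
  expect_equal(cs3[[1]]$score, 2000)

  # sub-min_cluster chains are discarded
  small <- data.frame(ref_start = 0, qry_start = 0, length = 900,
                      orientation = "+")
  expect_length(chain_anchors(small, min_cluster = 1000, qry_len = 2000), 0)
})

test_that("chaining matches an exhaustive subset-scoring oracle", {
  # 6 collinear anchors plus one off-diagonal outlier
  with_seed_local(11, {
    starts <- cumsum(c(0, rep(300, 5)))
    anc <- data.frame(ref_start = starts, qry_start = starts,
                      length = 250, orientation = "+")
    anc <- rbind(anc, data.frame(ref_start = 800, qry_start = 3000,
                                 length = 260, orientation = "+"))
  })
  cs <- chain_anchors(anc, max_gap = 500, min_cluster = 1000,
                      diag_diff = 20, qry_len = 5000)
  # exhaustive oracle: score every valid ordered subset
  n <- nrow(anc)
  best <- 0; best_set <- integer()
  subsets <- unlist(lapply(1:n, function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    ss <- ss[order(anc$ref_start[ss])]
    ok <- TRUE; sc <- anc$length[ss[1]]
    if (length(ss) > 1) {
      for (t in 2:length(ss)) {
        i <- ss[t]; j <- ss[t - 1]
        rg <- anc$ref_start[i] - (anc$ref_start[j] + anc$length[j])
        qg <- anc$qry_start[i] - (anc$qry_start[j] + anc$length[j])
        dd <- abs((anc$ref_start[i] - anc$qry_start[i]) -
                    (anc$ref_start[j] - anc$qry_start[j]))
        if (rg > 500 || qg > 500 || dd > 20 || rg < -20 || qg < -20) {
          ok <- FALSE; break
        }
        sc <- sc + anc$length[i] - max(rg, qg, 0) / 100
      }
    }
    if (ok && sum(anc$length[ss]) >= 1000 && sc > best) {
      best <- sc; best_set <- ss
    }
  }
  expect_equal(sort(best_set), 1:6)  # outlier excluded by the oracle
  top <- which.max(vapply(cs, `[[`, numeric(1), "score"))
  expect_equal(nrow(cs[[top]]$anchors), 6)
  expect_equal(sum(cs[[top]]$anchors$length), sum(anc$length[1:6]))
})

test_that("within-chain gaps classify by the Assemblytics rule table", {
  ref <- with_seed_local(7, random_dna(3000))
  mk_chain <- function(a2_ref, a2_qry) {
    structure(list(anchors = data.frame(ref_start = c(0, a2_ref),
                                        qry_start = c(0, a2_qry),
                                        length = c(1000, 1000)),
                   ref_start = 0, ref_end = a2_ref + 1000,
                   qry_start = 0, qry_end = a2_qry + 1000,
                   orientation = "+", score = 2000, qry_len = 5000),
              class = "anchor_chain")
  }
  # r = 0, q = 120 -> INS of 120 with its sequence
  qry <- paste0(substr(ref, 1, 1000), with_seed_local(8, random_dna(120)),
                substr(ref, 1001, 3000))
  v <- gap_variants(mk_chain(1000, 1120), ref, qry, min_sv = 50)
  expect_equal(v$type, "INS")
  expect_equal(v$length, 120)
  expect_equal(nchar(v$seq), 120)
  expect_identical(v$seq, substr(qry, 1001, 1120))
  # r = 30, q = 0 -> below the 50 bp floor, nothing
  v2 <- gap_variants(mk_chain(1030, 1000), ref, ref, min_sv = 50)
  expect_equal(nrow(v2), 0)
  # r = 200, q = 180 -> DIV of length max(r, q) = 200
  v3 <- gap_variants(mk_chain(1200, 1180), ref, ref, min_sv = 50)
  expect_equal(v3$type, "DIV")
  expect_equal(v3$length, 200)
})

test_that("no emitted variant is shorter than min_sv", {
  fx <- fix_small_pair()
  pv <- genome_pair_variants(fx$anc, fx$genome, min_sv = 50)
  expect_true(all(pv$length >= 50))
})

test_that("rearrangement detection recovers planted INV and TRA", {
  fx <- fix_small_pair()
  pv <- genome_pair_variants(fx$anc, fx$genome)
  ev <- fx$ev
  calls <- data.frame(type = pv$type, chrom = pv$ref_chrom,
                      pos = pv$ref_start, length = pv$length)
  inv <- ev[ev$type == "INV", ]
  expect_true(all(events_recovered(inv, calls, list(INV = "INV"),
                                   pos_tol = 50, len_tol = 50)))
  tra <- ev[ev$type == "TRA", ]
  expect_true(all(events_recovered(tra, calls, list(TRA = "TRA"),
                                   pos_tol = 50, len_tol = 50)))
  # collinear-only pair: no rearrangements at all
  anc <- fx$anc
  pv0 <- genome_pair_variants(anc, anc)
  expect_equal(nrow(pv0[pv0$type %in% c("INV", "TRA"), ]), 0)
})

test_that("planted INS/DEL/DIV are recovered with type and length", {
  fx <- fix_small_pair()
  pv <- genome_pair_variants(fx$anc, fx$genome)
  calls <- data.frame(type = pv$type, chrom = pv$ref_chrom,
                      pos = pv$ref_start, length = pv$length)
  ev <- fx$ev[fx$ev$type %in% c("INS", "DEL", "DIV"), ]
  rec <- events_recovered(ev, calls,
                          list(INS = "INS", DEL = "DEL", DIV = "DIV"))
  expect_true(all(rec))
})
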