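test_that("build_transcript validates structure with distinct errors", {
  ok <- make_model(c(120, 84, 96, 87, 111))
  expect_s3_class(ok, "transcript_model")
  expect_equal(ok$cds_length, 498)
  expect_equal(nrow(ok$introns), 4)

  single <- make_model(300)
  expect_equal(nrow(single$introns), 0)
  expect_equal(single$cds_length, 300)

  base <- list(transcript_id = "T", gene_symbol = "G", strand = "+",
               exons = data.frame(genomic_start = c(1001, 1120),
                                  genomic_end = c(1120, 1200)),
               cds_start = 1, cds_end = 201)
  expect_error(build_transcript(base), "overlapping exons")

  bad_frame <- base
  bad_frame$exons <- data.frame(genomic_start = c(1001, 2001),
                                genomic_end = c(1100, 2100))
  bad_frame$cds_end <- 200
  expect_error(build_transcript(bad_frame), "not divisible by 3")

  outside <- bad_frame
  outside$cds_end <- 300
  expect_error(build_transcript(outside), "CDS outside exons")

  touching <- base
  touching$exons <- data.frame(genomic_start = c(1001, 1101),
                               genomic_end = c(1100, 1201))
  touching$cds_end <- 201
  expect_error(build_transcript(touching), "zero-length intron")
})

test_that("plus-strand cDNA-to-genomic mapping hits exon boundaries exactly", {
  m <- make_model(c(120, 120), intron_len = 2000)
  expect_equal(map_c_to_genomic(m, 120), 1120)
  expect_equal(map_c_to_genomic(m, 120, 1), 1121)
  expect_equal(map_c_to_genomic(m, 121, -1), 3120)
  expect_error(map_c_to_genomic(m, 120, 2001), "exceeds intron")
  expect_error(map_c_to_genomic(m, 60, 1), "last base")
  expect_error(map_c_to_genomic(m, 500), "outside CDS")
})

test_that("mapping agrees with an exhaustive position walk on both strands", {
  for (strand in c("+", "-")) {
    m <- make_model(c(90, 84, 120), intron_len = c(70, 55), strand = strand,
                    utr5 = 12, utr3 = 21,
                    sequence = NULL)
    walk <- oracle_t2g_table(m)
    for (t in seq_len(m$transcript_length)) {
      cc <- asotriage:::t_to_c(m, t)
      expect_identical(map_c_to_genomic(m, cc$pos, 0, cc$region), walk[t])
    }
    # every intronic base: anchor at the flanking boundary, both signs
    for (i in seq_len(nrow(m$introns))) {
      donor_t <- m$exons$t_end[i]
      acceptor_t <- m$exons$t_start[i + 1]
      d_cc <- asotriage:::t_to_c(m, donor_t)
      a_cc <- asotriage:::t_to_c(m, acceptor_t)
      len <- m$introns$length[i]
      sgn <- if (strand == "+") 1L else -1L
      for (k in seq_len(len)) {
        expect_identical(map_c_to_genomic(m, d_cc$pos, k, d_cc$region),
                         walk[donor_t] + k * sgn)
        expect_identical(map_c_to_genomic(m, a_cc$pos, -k, a_cc$region),
                         walk[acceptor_t] - k * sgn)
      }
    }
  }
})

test_that("genomic-to-cDNA inverts the forward map over the whole span", {
  m <- make_model(c(90, 84, 120), intron_len = c(61, 44), utr5 = 9, utr3 = 15)
  span <- range(c(m$exons$genomic_start, m$exons$genomic_end))
  for (g in seq(span[1], span[2])) {
    loc <- map_genomic_to_c(m, g)
    expect_identical(map_c_to_genomic(m, loc$pos, loc$offset, loc$region), g)
  }
  expect_error(map_genomic_to_c(m, span[1] - 1), "outside transcript span")
  expect_error(map_genomic_to_c(m, span[2] + 1), "outside transcript span")
})

test_that("odd-length intron midpoint anchors at the donor side", {
  m <- make_model(c(90, 90), intron_len = 61)
  mid_g <- m$exons$genomic_end[1] + 31  # donor index 31 == acceptor index 31
  loc <- map_genomic_to_c(m, mid_g)
  expect_gt(loc$offset, 0)
  expect_equal(loc$offset, 31)
  # one base further is closer to the acceptor
  loc2 <- map_genomic_to_c(m, mid_g + 1)
  expect_lt(loc2$offset, 0)
  expect_equal(loc2$offset, -30)
})

test_that("exon coding lengths respect UTRs and sum to the CDS", {
  m <- make_model(c(80, 84, 94), utr5 = 40, utr3 = 30)
  # first exon is 120 nt with CDS starting at its 41st base
  expect_equal(m$exons$length[1], 120)
  expect_equal(exon_coding_length(m, 1), 80)
  expect_equal(exon_coding_length(m, 2), 84)
  expect_error(exon_coding_length(m, 4), "out of range")
  total <- sum(vapply(1:3, function(i) exon_coding_length(m, i), numeric(1)))
  expect_equal(total, m$cds_length)
  expect_equal(m$cds_length %% 3, 0)
})

test_that("internal coding exon excludes first/last coding and pure-UTR exons", {
  # last exon entirely 3'UTR: CDS ends inside exon 3 of 4
  m <- build_transcript(list(
    transcript_id = "T", gene_symbol = "G", strand = "+",
    exons = data.frame(genomic_start = c(1001, 2001, 3001, 4001),
                       genomic_end = c(1100, 2100, 3100, 4200)),
    cds_start = 21, cds_end = 221))
  expect_false(is_internal_coding_exon(m, 1))  # holds the start codon
  expect_true(is_internal_coding_exon(m, 2))
  expect_false(is_internal_coding_exon(m, 3))  # holds the stop codon
  expect_false(is_internal_coding_exon(m, 4))  # pure 3'UTR
  expect_equal(exon_coding_length(m, 4), 0)
})

test_that("strand reversal leaves all transcript-coordinate answers unchanged", {
  seq <- make_cds_sequence(100)
  for (args in list(list(utr5 = 0, utr3 = 0), list(utr5 = 18, utr3 = 27))) {
    pad <- args$utr5 + args$utr3
    full_seq <- paste0(strrep("A", args$utr5), seq, strrep("T", args$utr3))
    mp <- make_model(c(120, 84, 96), intron_len = c(900, 450),
                     utr5 = args$utr5, utr3 = args$utr3, sequence = full_seq)
    mm <- make_model(c(120, 84, 96), intron_len = c(900, 450), strand = "-",
                     utr5 = args$utr5, utr3 = args$utr3, sequence = full_seq)
    for (i in 1:3) {
      expect_equal(exon_coding_length(mp, i), exon_coding_length(mm, i))
      expect_equal(is_internal_coding_exon(mp, i),
                   is_internal_coding_exon(mm, i))
    }
    for (raw in c("c.120+2A>G", "c.121-30A>G", "c.150G>A", "c.204+120A>G")) {
      v <- parse_hgvs_c(raw)
      expect_equal(distance_to_nearest_splice_site(mp, v),
                   distance_to_nearest_splice_site(mm, v), info = raw)
      expect_equal(classify_region(mp, v)$primary_class,
                   classify_region(mm, v)$primary_class, info = raw)
    }
  }
})

test_that("sequence-requiring operations fail specifically without sequence", {
  m <- make_model(c(120, 84, 96))
  expect_error(derive_protein_consequence(m, parse_hgvs_c("c.10A>G")),
               "sequence required")
  expect_error(reconstruct_junction(m, 2), "sequence required")
})
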