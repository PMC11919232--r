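# long-intron model: 600-nt exons around a 18,400-nt intron so window sweeps
# on either side of intron 1 never feel the opposite junction
long_intron_model <- function() {
  make_model(c(600, 600), intron_len = 18400)
}

test_that("archetypal offsets get their documented primary classes", {
  m <- long_intron_model()
  cases <- list(
    list(raw = "c.600+2T>A", class = "CANONICAL_DONOR"),
    list(raw = "c.601-2A>G", class = "CANONICAL_ACCEPTOR"),
    list(raw = "c.600+5T>A", class = "DONOR_REGION"),
    list(raw = "c.601-3C>G", class = "ACCEPTOR_REGION"),
    list(raw = "c.601-27T>C", class = "BRANCH_POINT_WINDOW"),
    list(raw = "c.601-60T>C", class = "PROXIMAL_INTRONIC"),
    list(raw = "c.601-1340A>G", class = "DEEP_INTRONIC"),
    list(raw = "c.300G>A", class = "EXONIC"))
  for (cs in cases) {
    rep <- classify_region(m, parse_hgvs_c(cs$raw))
    expect_equal(rep$primary_class, cs$class, info = cs$raw)
    expect_true(rep$primary_class %in% rep$tags, info = cs$raw)
  }
})

test_that("intronic offsets 1..200 partition into contiguous runs, none unclassified", {
  m <- long_intron_model()
  donor_side <- vapply(1:200, function(k)
    classify_region(m, parse_hgvs_c(sprintf("c.600+%dA>G", k)))$primary_class,
    character(1))
  r <- rle(donor_side)
  expect_equal(r$values, c("CANONICAL_DONOR", "DONOR_REGION",
                           "PROXIMAL_INTRONIC", "DEEP_INTRONIC"))
  expect_equal(r$lengths, c(2, 4, 94, 100))

  acceptor_side <- vapply(1:200, function(k)
    classify_region(m, parse_hgvs_c(sprintf("c.601-%dA>G", k)))$primary_class,
    character(1))
  r <- rle(acceptor_side)
  expect_equal(r$values, c("CANONICAL_ACCEPTOR", "ACCEPTOR_REGION",
                           "BRANCH_POINT_WINDOW", "PROXIMAL_INTRONIC",
                           "DEEP_INTRONIC"))
  expect_equal(r$lengths, c(2, 18, 20, 60, 100))
})

test_that("window extents are recovered behaviourally from tag sweeps", {
  m <- long_intron_model()
  donor_tags <- vapply(1:60, function(k)
    "DONOR_REGION" %in%
      classify_region(m, parse_hgvs_c(sprintf("c.600+%dA>G", k)))$tags,
    logical(1))
  expect_equal(which(donor_tags), 1:6)

  acc_tags <- vapply(1:60, function(k)
    "ACCEPTOR_REGION" %in%
      classify_region(m, parse_hgvs_c(sprintf("c.601-%dA>G", k)))$tags,
    logical(1))
  expect_equal(which(acc_tags), 1:20)

  branch_tags <- vapply(1:60, function(k)
    "BRANCH_POINT_WINDOW" %in%
      classify_region(m, parse_hgvs_c(sprintf("c.601-%dA>G", k)))$tags,
    logical(1))
  expect_equal(which(branch_tags), 18:40)

  deep <- vapply(1:200, function(k)
    classify_region(m,
      parse_hgvs_c(sprintf("c.600+%dA>G", k)))$primary_class ==
      "DEEP_INTRONIC", logical(1))
  expect_equal(min(which(deep)), 101)
})

test_that("branch window overlapping the acceptor region keeps both tags", {
  m <- long_intron_model()
  for (k in 18:20) {
    rep <- classify_region(m, parse_hgvs_c(sprintf("c.601-%dA>G", k)))
    expect_equal(rep$primary_class, "ACCEPTOR_REGION")
    expect_true("BRANCH_POINT_WINDOW" %in% rep$tags)
  }
})

test_that("splice-site distances match per-position enumeration in an exon", {
  m <- make_model(c(120, 84, 96), intron_len = c(3000, 3000))
  # exon 2 spans coding 121..204, length 84
  for (idx in 1:84) {
    v <- parse_hgvs_c(sprintf("c.%dA>G", 120 + idx))
    expect_equal(distance_to_nearest_splice_site(m, v),
                 min(idx, 84 - idx + 1), info = idx)
  }
  expect_equal(distance_to_nearest_splice_site(
    m, parse_hgvs_c("c.162A>G")), 42)  # 42nd base of exon 2
  expect_equal(distance_to_nearest_splice_site(
    m, parse_hgvs_c("c.204+1A>G")), 1)
  expect_equal(distance_to_nearest_splice_site(
    m, parse_hgvs_c("c.121-1340A>G")), 1340)
})

test_that("distance along an intron is 1-Lipschitz", {
  m <- long_intron_model()
  d <- vapply(1:500, function(k) distance_to_nearest_splice_site(
    m, parse_hgvs_c(sprintf("c.600+%dA>G", k))), numeric(1))
  expect_true(all(abs(diff(d)) <= 1))
  d2 <- vapply(1:500, function(k) distance_to_nearest_splice_site(
    m, parse_hgvs_c(sprintf("c.601-%dA>G", k))), numeric(1))
  expect_true(all(abs(diff(d2)) <= 1))
})

test_that("user-supplied branch points override the positional window", {
  m <- long_intron_model()
  bp <- list("1" = 25)
  rep25 <- classify_region(m, parse_hgvs_c("c.601-25A>G"),
                           branch_points = bp)
  expect_true("BRANCH_POINT_WINDOW" %in% rep25$tags)
  rep30 <- classify_region(m, parse_hgvs_c("c.601-30A>G"),
                           branch_points = bp)
  expect_false("BRANCH_POINT_WINDOW" %in% rep30$tags)
  expect_equal(rep30$distance_to_branch_window, 5)
  # without the override offset -30 is inside the default window
  expect_true("BRANCH_POINT_WINDOW" %in%
                classify_region(m, parse_hgvs_c("c.601-30A>G"))$tags)
})

test_that("ranged variants straddling a junction take the most constraining class", {
  m <- long_intron_model()
  v <- parse_hgvs_c("c.599_600+3del")
  rep <- classify_region(m, v)
  expect_true("SPANS_JUNCTION" %in% rep$tags)
  expect_equal(rep$primary_class, "CANONICAL_DONOR")
})

test_that("exonic junction proximity uses the recommended clearance", {
  m <- long_intron_model()
  near <- classify_region(m, parse_hgvs_c("c.587A>G"))   # 14 nt from donor
  far <- classify_region(m, parse_hgvs_c("c.586A>G"))    # 15 nt from donor
  expect_true(near$near_junction_exonic)
  expect_false(far$near_junction_exonic)
  # exonic arm of the donor region: last 3 exon bases
  expect_true("DONOR_REGION" %in%
                classify_region(m, parse_hgvs_c("c.598A>G"))$tags)
  expect_false("DONOR_REGION" %in%
                 classify_region(m, parse_hgvs_c("c.597A>G"))$tags)
  # first exon base of an internal exon carries the acceptor-region tag
  expect_true("ACCEPTOR_REGION" %in%
                classify_region(m, parse_hgvs_c("c.601A>G"))$tags)
})
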