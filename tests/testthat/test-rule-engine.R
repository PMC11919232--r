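sweep_model <- function() make_model(c(600, 600), intron_len = 18400)

test_that("cryptic-splice verdicts split into three distance regimes", {
  m <- sweep_model()
  verdicts <- lapply(1:200, function(k)
    evaluate_cryptic_splice(m, parse_hgvs_c(sprintf("c.600+%dA>G", k)),
                            cryptic_ev()))
  cats <- vapply(verdicts, `[[`, character(1), "category")
  r <- rle(cats)
  expect_equal(r$values, c("NOT_AMENABLE", "CONDITIONALLY_AMENABLE",
                           "AMENABLE_CRYPTIC_SPLICE_BLOCK"))
  expect_equal(r$lengths, c(4, 10, 186))
  # the deep-intronic "ideal" note appears only beyond 100 nt
  has_deep <- vapply(verdicts, function(v)
    any(grepl("Deep intronic", v$notes)), logical(1))
  expect_equal(min(which(has_deep)), 101)
  # regime boundaries move with the config
  cfg <- triage_config(hard_cutoff_nt = 8, recommended_cutoff_nt = 20)
  cats2 <- vapply(1:40, function(k)
    evaluate_cryptic_splice(m, parse_hgvs_c(sprintf("c.600+%dA>G", k)),
                            cryptic_ev(), config = cfg)$category,
    character(1))
  expect_equal(rle(cats2)$lengths[1:2], c(7, 12))
})

test_that("cryptic-splice hard gates reject canonical, branch and destroyed splicing", {
  m <- sweep_model()
  expect_equal(evaluate_cryptic_splice(
    m, parse_hgvs_c("c.600+2T>A"), cryptic_ev())$category, "NOT_AMENABLE")
  expect_equal(evaluate_cryptic_splice(
    m, parse_hgvs_c("c.601-27T>C"), cryptic_ev())$category, "NOT_AMENABLE")
  expect_equal(evaluate_cryptic_splice(
    m, parse_hgvs_c("c.601-1340A>G"),
    cryptic_ev(intact = "no"))$category, "NOT_AMENABLE")
  expect_equal(evaluate_cryptic_splice(
    m, parse_hgvs_c("c.601-1340A>G"),
    cryptic_ev(assay = "none"))$category, "INSUFFICIENT_EVIDENCE")
  expect_error(evaluate_cryptic_splice(
    m, parse_hgvs_c("c.300A>G"), splice_evidence("none", "yes", "rna_seq")),
    "requires cryptic-splice evidence")
})

test_that("exonic cryptic targets carry skip-risk and nonsynonymous cautions", {
  b <- build_hypothetical_transcript()
  syn <- evaluate_cryptic_splice(b$model, parse_hgvs_c("c.342G>A"),
                                 cryptic_ev(assay = "minigene"))
  expect_equal(syn$category, "AMENABLE_CRYPTIC_SPLICE_BLOCK")
  expect_true(any(grepl("skipping of the exon altogether", syn$warnings)))
  expect_false(any(grepl("Nonsynonymous", syn$warnings)))

  mis <- evaluate_cryptic_splice(b$model, parse_hgvs_c("c.340C>A"),
                                 cryptic_ev(assay = "minigene"))
  expect_true(any(grepl("Nonsynonymous", mis$warnings)))
})

test_that("evidence naming an untouchable exon is an input-consistency error", {
  m <- sweep_model()
  ev <- splice_evidence("cryptic_donor_created", "yes", "rna_seq",
                        affected_exon_index = 9L)
  expect_error(evaluate_cryptic_splice(m, parse_hgvs_c("c.600+50A>G"), ev),
               "evidence/variant mismatch")
})

test_that("truncating-variant gates fire in documented order", {
  b <- build_hypothetical_transcript()
  m <- b$model
  v <- parse_hgvs_c("c.448C>T")

  amen <- evaluate_truncating(m, v, simulate_exon_skip(m, 5, b$domains))
  expect_equal(amen$category, "AMENABLE_EXON_SKIP")
  expect_true(any(grepl("Large in-frame removal", amen$warnings)))  # 12.6%

  # same exon, synthetic domain covering it
  dom <- c(b$domains, list(domain_annotation("covers e5", 400, 500)))
  blocked <- evaluate_truncating(m, v, simulate_exon_skip(m, 5, dom))
  expect_equal(blocked$category, "NOT_AMENABLE")
  expect_equal(blocked$trace$node_id[nrow(blocked$trace)], "domain_gate")

  # first and last coding exons are never skippable
  first <- evaluate_truncating(m, parse_hgvs_c("c.10C>A"),
                               simulate_exon_skip(m, 1))
  expect_equal(first$category, "NOT_AMENABLE")
  expect_equal(first$trace$node_id[nrow(first$trace)], "internal_exon")
  last <- evaluate_truncating(m, parse_hgvs_c("c.940del"),
                              simulate_exon_skip(m, 10))
  expect_equal(last$category, "NOT_AMENABLE")

  # out-of-frame exon: rejection plus multi-exon note
  oof <- evaluate_truncating(m, parse_hgvs_c("c.700del"),
                             simulate_exon_skip(m, 8))
  expect_equal(oof$category, "NOT_AMENABLE")
  expect_true(any(grepl("multi-exon", oof$notes, ignore.case = TRUE)))

  expect_error(evaluate_truncating(m, v, NULL), "missing skip simulation")
})

test_that("junction stop codon blocks an otherwise skippable exon", {
  ov <- list("24" = "TCC", "47" = "AGA")  # fused TGA after skipping exon 2
  m <- make_model(c(70, 69, 71), sequence = make_cds_sequence(70, ov,
                                                              seed = 3L))
  s <- simulate_exon_skip(m, 2)
  expect_equal(s$junction_event, "stop_gained")
  v <- evaluate_truncating(m, parse_hgvs_c("c.100del"), s)
  expect_equal(v$category, "NOT_AMENABLE")
  expect_equal(v$trace$node_id[nrow(v$trace)], "junction_stop")
})

test_that("pathogenic exon-deletion reports block skipping unless overridden", {
  b <- build_hypothetical_transcript()
  m <- b$model
  v <- parse_hgvs_c("c.448C>T")
  s <- simulate_exon_skip(m, 5, population_evidence =
                            population_evidence(NA, TRUE))
  expect_equal(evaluate_truncating(m, v, s)$category, "NOT_AMENABLE")
  cfg <- triage_config(skip_override_justification =
                         "reported deletion carriers show a much milder phenotype")
  over <- evaluate_truncating(m, v, s, cfg)
  expect_equal(over$category, "CONDITIONALLY_AMENABLE")
  expect_true(any(grepl("override", over$notes)))
  # healthy-population skipping is supportive, not gating
  s2 <- simulate_exon_skip(m, 5, population_evidence =
                             population_evidence(TRUE, NA))
  ok <- evaluate_truncating(m, v, s2)
  expect_equal(ok$category, "AMENABLE_EXON_SKIP")
  expect_true(any(grepl("healthy individuals", ok$notes)))
})

test_that("hotspot scoring counts, majority rule and rejection logging", {
  v <- parse_hgvs_c("c.640G>C")
  empty <- hotspot_score(v, NULL, c(598, 681))
  expect_equal(empty$n_pathogenic_missense_in_exon, 0)
  expect_false(empty$is_hotspot)
  expect_false(empty$lof_evidence_nearby)

  five <- data.frame(position_c = c(600, 620, 640, 660, 680),
                     consequence = "missense",
                     classification = "pathogenic",
                     functional_lof = NA)
  expect_true(hotspot_score(v, five, c(598, 681))$is_hotspot)

  mixed <- data.frame(position_c = c(600, 620, 610, 630, 650, 670),
                      consequence = c("missense", "missense", rep("nonsense", 4)),
                      classification = "pathogenic",
                      functional_lof = NA)
  hs <- hotspot_score(v, mixed, c(598, 681))
  expect_equal(hs$n_pathogenic_missense_in_exon, 2)
  expect_false(hs$is_hotspot)   # 2/6 below the majority fraction

  malformed <- rbind(five,
                     data.frame(position_c = "x", consequence = "missense",
                                classification = "pathogenic",
                                functional_lof = NA),
                     data.frame(position_c = 650, consequence = "weird",
                                classification = "pathogenic",
                                functional_lof = NA))
  expect_message(hs2 <- hotspot_score(v, malformed, c(598, 681)),
                 "rejecting table row")
  expect_equal(nrow(hs2$rejected_rows), 2)
  expect_true(hs2$is_hotspot)   # valid rows still counted

  near_lof <- data.frame(position_c = 700, consequence = "missense",
                         classification = "pathogenic", functional_lof = TRUE)
  expect_true(hotspot_score(v, near_lof, c(598, 681))$lof_evidence_nearby)
  # outside the +/-90 nt window the flag does not fire
  far_lof <- data.frame(position_c = 900, consequence = "missense",
                        classification = "pathogenic", functional_lof = TRUE)
  expect_false(hotspot_score(v, far_lof, c(598, 681))$lof_evidence_nearby)
})

test_that("missense path is capped at conditional and gated by hotspot/LoF", {
  b <- build_hypothetical_transcript()
  m <- b$model
  v8 <- parse_hgvs_c("c.640G>C")
  s <- simulate_exon_skip(m, 7, b$domains)
  hs_hot <- hotspot_score(v8, b$pathogenic_table,
                          asotriage:::exon_coding_interval(m, 7))
  expect_true(hs_hot$is_hotspot)
  expect_equal(evaluate_missense(m, v8, s, hs_hot)$category, "NOT_AMENABLE")

  hs_empty <- hotspot_score(v8, NULL, asotriage:::exon_coding_interval(m, 7))
  surv <- evaluate_missense(m, v8, s, hs_empty)
  expect_equal(surv$category, "CONDITIONALLY_AMENABLE")  # never auto-amenable
  expect_true(any(grepl("expert review", surv$required_followups,
                        ignore.case = TRUE)))

  lof_only <- data.frame(position_c = 650, consequence = "missense",
                         classification = "pathogenic", functional_lof = TRUE)
  hs_lof <- hotspot_score(v8, lof_only, asotriage:::exon_coding_interval(m, 7))
  expect_false(hs_lof$is_hotspot)
  expect_equal(evaluate_missense(m, v8, s, hs_lof)$category, "NOT_AMENABLE")

  # PPP2R5D-style: in-frame exon, nearby pathogenic missense with shown LoF
  expect_equal(
    triage(m, v8, splice_evidence("none", "yes", "rna_seq"),
           pathogenic_table = lof_only)$category,
    "NOT_AMENABLE")
  expect_error(evaluate_missense(m, v8, s, NULL), "missing hotspot report")
})

test_that("allele-specificity warning is gated on category and zygosity", {
  b <- build_hypothetical_transcript()
  het <- b$variants[[6]]
  v_het <- triage(b$model, het$variant, het$evidence, domains = b$domains)
  expect_true(any(grepl("allele-selective", v_het$warnings)))

  hom <- parse_hgvs_c("c.448C>T", zygosity = "homozygous")
  v_hom <- triage(b$model, hom, het$evidence, domains = b$domains)
  expect_equal(v_hom$category, "AMENABLE_EXON_SKIP")
  expect_false(any(grepl("allele-selective", v_hom$warnings)))

  cryptic <- triage(b$model, b$variants[[3]]$variant,
                    b$variants[[3]]$evidence)
  expect_true(any(grepl("Allele specificity is not needed", cryptic$notes)))
})

test_that("patient checklist requires all five criteria", {
  ok <- patient_profile("life_threatening", TRUE, "brain", TRUE, TRUE)
  expect_true(evaluate_patient(ok)$eligible)
  expect_true(evaluate_patient(patient_profile(
    "severely_debilitating", TRUE, "eye", TRUE, TRUE))$eligible)
  expect_false(evaluate_patient(patient_profile(
    "life_threatening", TRUE, "other", TRUE, TRUE))$eligible)
  expect_false(evaluate_patient(patient_profile(
    "life_threatening", TRUE, "brain", FALSE, TRUE))$eligible)
  expect_false(evaluate_patient(patient_profile(
    "other", TRUE, "brain", TRUE, TRUE))$eligible)
  expect_error(patient_profile("life_threatening", TRUE, "brain", TRUE),
               "all five")
  el <- evaluate_patient(patient_profile("life_threatening", TRUE, "spinal_cord",
                                         TRUE, FALSE))
  expect_false(el$eligible)
  expect_equal(sum(!el$trace$satisfied), 1)
})

test_that("triage routes out-of-scope and unconfirmed inputs correctly", {
  b <- build_hypothetical_transcript()
  m <- b$model
  # declared GoF mechanism
  gof <- triage(m, parse_hgvs_c("c.448C>T"),
                splice_evidence("none", "yes", "rna_seq"), mechanism = "gof")
  expect_equal(gof$category, "OUT_OF_SCOPE")
  # UTR positional variant
  utr <- triage(m, parse_hgvs_c("c.*45A>G"),
                splice_evidence("none", "yes", "rna_seq"))
  expect_equal(utr$category, "OUT_OF_SCOPE")
  # unknown splicing outcome
  unk <- triage(m, parse_hgvs_c("c.301-1340A>G"), splice_evidence())
  expect_equal(unk$category, "INSUFFICIENT_EVIDENCE")
  # splice claim without assay
  noassay <- triage(m, parse_hgvs_c("c.205+2T>A"),
                    splice_evidence("exon_skipping", "no", "none", 2L))
  expect_equal(noassay$category, "INSUFFICIENT_EVIDENCE")
  # synonymous variant with no splice effect: no in-scope LoF mechanism
  syn <- triage(m, parse_hgvs_c("c.342G>A"),
                splice_evidence("none", "yes", "rna_seq"))
  expect_equal(syn$category, "OUT_OF_SCOPE")
  # intronic variant shown not to affect splicing
  quiet <- triage(m, parse_hgvs_c("c.301-500A>G"),
                  splice_evidence("none", "yes", "rna_seq"))
  expect_equal(quiet$category, "OUT_OF_SCOPE")
})

test_that("regulatory-element disruption rejects with the exon-inclusion warning", {
  b <- build_hypothetical_transcript()
  a5 <- b$variants[[5]]
  v <- triage(b$model, a5$variant, a5$evidence)
  expect_equal(v$category, "NOT_AMENABLE")
  expect_true(any(grepl("exon inclusion", v$warnings)))
  expect_true(any(grepl("out-of-frame", v$notes)))  # exon 8 is out of frame
})

test_that("triage is deterministic: identical inputs, identical traces", {
  b <- build_hypothetical_transcript()
  for (a in b$variants[c(1, 3, 6, 8)]) {
    v1 <- triage(b$model, a$variant, a$evidence, domains = b$domains,
                 pathogenic_table = b$pathogenic_table)
    v2 <- triage(b$model, a$variant, a$evidence, domains = b$domains,
                 pathogenic_table = b$pathogenic_table)
    expect_identical(v1, v2)
  }
})

test_that("adding a failed mandatory condition never improves the category", {
  b <- build_hypothetical_transcript()
  m <- b$model
  base_args <- list(model = m, v = b$variants[[6]]$variant,
                    evidence = b$variants[[6]]$evidence,
                    domains = b$domains)
  base <- do.call(triage, base_args)
  harms <- list(
    list(domains = c(b$domains, list(domain_annotation("x", 390, 500)))),
    list(population_evidence = population_evidence(NA, TRUE)),
    list(evidence = splice_evidence("exon_skipping", "no", "rna_seq", 5L)))
  for (h in harms) {
    args <- utils::modifyList(base_args, h)
    worse <- do.call(triage, args)
    expect_gte(verdict_rank(worse$category), verdict_rank(base$category))
  }
  # randomized sweep over cryptic distances: degrading evidence never helps
  set.seed(5)
  sm <- sweep_model()
  for (k in sample(1:200, 25)) {
    v <- parse_hgvs_c(sprintf("c.600+%dA>G", k))
    good <- evaluate_cryptic_splice(sm, v, cryptic_ev())
    bad <- evaluate_cryptic_splice(sm, v, cryptic_ev(intact = "no"))
    expect_gte(verdict_rank(bad$category), verdict_rank(good$category))
  }
})

test_that("no amenable verdict coexists with a failed mandatory trace node", {
  b <- build_hypothetical_transcript()
  verdicts <- triage_bundle(b)
  mandatory <- c("internal_exon", "in_frame", "domain_gate", "junction_stop",
                 "population_gate", "canonical_site_gate",
                 "branch_point_gate", "canonical_intact", "distance_hard")
  for (v in verdicts) {
    if (!grepl("^AMENABLE", v$category)) next
    tr <- v$trace[v$trace$node_id %in% mandatory, ]
    expect_false(any(tr$answer %in% c("FALSE") &
                       tr$node_id %in% c("internal_exon", "in_frame",
                                         "canonical_intact")))
    expect_false(any(tr$answer %in% c("TRUE") &
                       tr$node_id %in% c("domain_gate", "junction_stop",
                                         "population_gate",
                                         "canonical_site_gate",
                                         "branch_point_gate")))
  }
})
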