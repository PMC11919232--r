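#' @title Synthetic fixtures
#' @description Deterministic generators for all test inputs: a hypothetical
#'   multi-exon transcript hosting the eight loss-of-function variant
#'   archetypes, surrogate-transcript encodings of four published real-life
#'   variants, and randomized transcripts for property tests. Everything is
#'   self-contained: no network access, no genome download.
#' @name fixtures
NULL

# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

random_sense_codons <- function(n) {
  sample(setdiff(all_codons(), STOP_CODONS), n, replace = TRUE)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the eight-archetype hypothetical transcript fixture
#'
#' A deterministic ten-exon plus-strand transcript (951-nt CDS, mixed exon
#' frames, deep introns of 3,000-5,200 nt, two functional-domain
#' annotations) carrying one variant of each archetype the decision trees
#' distinguish:
#' \enumerate{
#'   \item canonical splice-donor variant (+2) causing exon skipping;
#'   \item branch-point variant (-27);
#'   \item deep intronic cryptic-splice variant (-1340);
#'   \item exonic (synonymous) cryptic-splice variant, clear of junctions;
#'   \item exonic splice-enhancer disruption causing exon skipping;
#'   \item nonsense variant in an internal, in-frame, domain-free exon;
#'   \item missense variant in an in-frame exon inside a functional domain;
#'   \item missense variant in the middle of a pathogenic-missense hotspot.
#' }
#' Coordinates are invented but frozen (a fixed seed is baked in), so every
#' downstream result is bit-stable.
#'
#' @return A list of class \code{"fixture_bundle"}: \code{model} (with
#'   sequence), \code{variants} (eight entries of \code{archetype},
#'   \code{label}, \code{variant}, \code{evidence},
#'   \code{expected_category}), \code{domains}, \code{pathogenic_table}
#'   (rows supporting the hotspot archetype), and \code{conventions}
#'   metadata (exon ordinals count all exons, including non-coding ones).
#' @examples
#' b <- build_hypothetical_transcript()
#' length(b$variants)
#' @export
build_hypothetical_transcript <- function() {
  coding_len <- c(120, 85, 95, 87, 120, 90, 84, 100, 110, 60)
  utr5 <- 50
  utr3 <- 200
  exon_len <- coding_len
  exon_len[1] <- exon_len[1] + utr5
  exon_len[10] <- exon_len[10] + utr3
  intron_len <- c(3200, 4100, 5200, 3500, 3000, 3300, 3600, 3050, 4000)

  g <- 10001
  gs <- ge <- integer(10)
  for (i in 1:10) {
    gs[i] <- g
    ge[i] <- g + exon_len[i] - 1
    g <- ge[i] + 1 + if (i < 10) intron_len[i] else 0
  }

  n_codons <- sum(coding_len) / 3  # 317
  codons <- with_seed(20240418L, {
    cd <- random_sense_codons(n_codons)
    cd[1] <- "ATG"
    cd[n_codons] <- "TAA"
    # archetype anchor codons (coding positions 340-342, 448-450, 550-552,
    # 640-642, 700-702)
    cd[114] <- "CCG"  # c.342G>A -> CCA, synonymous (Pro)
    cd[150] <- "CAA"  # c.448C>T -> TAA, nonsense
    cd[184] <- "GAG"  # c.550G>A -> AAG, Glu>Lys missense
    cd[214] <- "GGG"  # c.640G>C -> CGG, Gly>Arg missense
    cd[234] <- "GCA"  # c.702A>G -> GCG, synonymous (Ala)
    cd
  })
  sequence <- with_seed(20240419L, paste0(
    random_bases(utr5), paste(codons, collapse = ""), random_bases(utr3)))

  model <- build_transcript(list(
    transcript_id = "HYP-TX-8V", gene_symbol = "HYPGENE", strand = "+",
    exons = data.frame(genomic_start = gs, genomic_end = ge),
    cds_start = utr5 + 1, cds_end = utr5 + sum(coding_len),
    sequence = sequence))

  domains <- list(
    domain_annotation("N-terminal catalytic domain", 60, 180, "fixture"),
    domain_annotation("substrate-binding domain", 520, 580, "fixture"))

  pathogenic_table <- data.frame(
    position_c = c(610, 616, 625, 655, 670, 620, 300),
    consequence = c(rep("missense", 5), "nonsense", "missense"),
    classification = c("pathogenic", "likely_pathogenic", "pathogenic",
                       "pathogenic", "likely_pathogenic", "pathogenic",
                       "benign"),
    functional_lof = c(FALSE, FALSE, TRUE, FALSE, NA, NA, NA),
    stringsAsFactors = FALSE)

  variants <- list(
    list(archetype = 1L, label = "canonical splice-donor variant",
         variant = parse_hgvs_c("c.205+2T>A"),
         evidence = splice_evidence("exon_skipping", "no", "rt_qpcr", 2L),
         expected_category = "NOT_AMENABLE"),
    list(archetype = 2L, label = "branch-point variant",
         variant = parse_hgvs_c("c.388-27T>C"),
         evidence = splice_evidence("cryptic_acceptor_created", "partial",
                                    "rt_qpcr", 5L),
         expected_category = "NOT_AMENABLE"),
    list(archetype = 3L, label = "deep intronic cryptic-splice variant",
         variant = parse_hgvs_c("c.301-1340A>G"),
         evidence = splice_evidence("cryptic_exon_inclusion", "yes",
                                    "rna_seq"),
         expected_category = "AMENABLE_CRYPTIC_SPLICE_BLOCK"),
    list(archetype = 4L, label = "exonic cryptic-splice variant (synonymous)",
         variant = parse_hgvs_c("c.342G>A"),
         evidence = splice_evidence("cryptic_donor_created", "yes",
                                    "minigene", 4L),
         expected_category = "AMENABLE_CRYPTIC_SPLICE_BLOCK"),
    list(archetype = 5L, label = "splice-enhancer disruption (synonymous)",
         variant = parse_hgvs_c("c.702A>G"),
         evidence = splice_evidence("exon_skipping", "no", "rna_seq", 8L),
         expected_category = "NOT_AMENABLE"),
    list(archetype = 6L, label = "nonsense variant, skippable exon",
         variant = parse_hgvs_c("c.448C>T", zygosity = "heterozygous"),
         evidence = splice_evidence("none", "yes", "rna_seq"),
         expected_category = "AMENABLE_EXON_SKIP"),
    list(archetype = 7L, label = "missense variant in functional domain",
         variant = parse_hgvs_c("c.550G>A"),
         evidence = splice_evidence("none", "yes", "rna_seq"),
         expected_category = "NOT_AMENABLE"),
    list(archetype = 8L, label = "missense variant in mutational hotspot",
         variant = parse_hgvs_c("c.640G>C"),
         evidence = splice_evidence("none", "yes", "rna_seq"),
         expected_category = "NOT_AMENABLE"))

  structure(list(model = model, variants = variants, domains = domains,
                 pathogenic_table = pathogenic_table,
                 conventions = list(
                   exon_ordinals = "all exons counted, including non-coding",
                   coordinates = "1-based inclusive; HGVS-c anchors")),
            class = "fixture_bundle")
}

#' Triage every archetype of a fixture bundle
#'
#' Convenience wrapper running [triage()] over all bundled variants with the
#' bundle's domains and pathogenic table.
#'
#' @param bundle A [build_hypothetical_transcript()] bundle.
#' @param config A [triage_config()].
#' @return A named list of \code{verdict} objects (one per archetype).
#' @export
triage_bundle <- function(bundle, config = triage_config()) {
  out <- lapply(bundle$variants, function(a)
    triage(bundle$model, a$variant, a$evidence, domains = bundle$domains,
           pathogenic_table = bundle$pathogenic_table, config = config))
  names(out) <- vapply(bundle$variants, function(a)
    paste0("archetype_", a$archetype), character(1))
  out
}

#' Surrogate-transcript encodings of four published variants
#'
#' Four real descriptors exercising the region classifier: a canonical
#' splice-donor variant (MFSD8 c.754+2T>A), a splice-acceptor-region
#' variant (COASY c.1486-3C>G), a branch-point variant (NUBPL c.815-27T>C)
#' and a deep intronic cryptic-splice variant (TIMMDC1 c.597-1340A>G).
#' The transcripts are synthetic surrogates with the correct exon/intron
#' geometry around each variant, not the RefSeq sequences: only offsets and
#' region classes are asserted against them.
#'
#' @return A list of entries with \code{gene}, \code{raw},
#'   \code{variant}, \code{model}, \code{expected_offset},
#'   \code{expected_class}.
#' @export
encode_worked_examples <- function() {
  surrogate <- function(id, e1_coding, e2_coding, intron) {
    build_transcript(list(
      transcript_id = id, gene_symbol = sub("-SURR$", "", id), strand = "+",
      exons = data.frame(
        genomic_start = c(1001, 1001 + e1_coding + intron),
        genomic_end = c(1000 + e1_coding,
                        1000 + e1_coding + intron + e2_coding)),
      cds_start = 1, cds_end = e1_coding + e2_coding))
  }
  list(
    list(gene = "MFSD8", raw = "c.754+2T>A",
         variant = parse_hgvs_c("c.754+2T>A"),
         model = surrogate("MFSD8-SURR", 754, 146, 2500),
         expected_offset = 2L, expected_class = "CANONICAL_DONOR"),
    list(gene = "COASY", raw = "c.1486-3C>G",
         variant = parse_hgvs_c("c.1486-3C>G"),
         model = surrogate("COASY-SURR", 1485, 315, 2500),
         expected_offset = -3L, expected_class = "ACCEPTOR_REGION"),
    list(gene = "NUBPL", raw = "c.815-27T>C",
         variant = parse_hgvs_c("c.815-27T>C"),
         model = surrogate("NUBPL-SURR", 814, 86, 3000),
         expected_offset = -27L, expected_class = "BRANCH_POINT_WINDOW"),
    list(gene = "TIMMDC1", raw = "c.597-1340A>G",
         variant = parse_hgvs_c("c.597-1340A>G"),
         model = surrogate("TIMMDC1-SURR", 596, 304, 5000),
         expected_offset = -1340L, expected_class = "DEEP_INTRONIC"))
}

#' Generate a random valid transcript model
#'
#' Reproducible given the seed; used for property tests (coordinate round
#' trips, junction-codon oracle sweeps).
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= 1).
#' @param exon_length_range,intron_length_range Sampling ranges (nt).
#' @param strand \code{"+"}, \code{"-"}, or \code{"random"}.
#' @param with_sequence Attach a random spliced sequence (start codon, sense
#'   codons, terminal stop)?
#' @return A \code{transcript_model}.
#' @export
generate_random_transcript <- function(seed, n_exons = 6,
                                       exon_length_range = c(40, 200),
                                       intron_length_range = c(300, 4000),
                                       strand = "random",
                                       with_sequence = TRUE) {
  if (n_exons < 1) stop("n_exons must be >= 1")
  if (exon_length_range[1] < 10)
    stop("infeasible length constraints: exons must be >= 10 nt here")
  with_seed(seed, {
    if (strand == "random") strand <- sample(c("+", "-"), 1)
    exon_len <- sample(seq(exon_length_range[1], exon_length_range[2]),
                       n_exons, replace = TRUE)
    intron_len <- if (n_exons > 1)
      sample(seq(intron_length_range[1], intron_length_range[2]),
             n_exons - 1, replace = TRUE) else integer(0)
    tx_len <- sum(exon_len)
    # CDS: leave room for short UTRs and force length divisible by 3
    utr5 <- sample(0:min(30, exon_len[1] - 10), 1)
    utr3_room <- exon_len[n_exons] - 10 - if (n_exons == 1) utr5 else 0
    utr3 <- sample(0:max(min(30, utr3_room), 0), 1)
    cds_len <- tx_len - utr5 - utr3
    utr3 <- utr3 + cds_len %% 3
    cds_len <- cds_len - cds_len %% 3
    if (cds_len < 6) stop("infeasible length constraints: CDS too short")

    g0 <- sample(1000:100000, 1)
    gs <- ge <- integer(n_exons)
    g <- g0
    for (i in seq_len(n_exons)) {
      gs[i] <- g
      ge[i] <- g + exon_len[i] - 1
      g <- ge[i] + 1 + if (i < n_exons) intron_len[i] else 0
    }
    sequence <- NULL
    if (with_sequence) {
      n_codons <- cds_len / 3
      codons <- random_sense_codons(n_codons)
      codons[1] <- "ATG"
      codons[n_codons] <- sample(STOP_CODONS, 1)
      sequence <- paste0(random_bases(utr5), paste(codons, collapse = ""),
                         random_bases(utr3))
    }
    build_transcript(list(
      transcript_id = sprintf("RND-%d", seed), gene_symbol = "RNDGENE",
      strand = strand,
      exons = data.frame(genomic_start = gs, genomic_end = ge),
      cds_start = utr5 + 1, cds_end = utr5 + cds_len,
      sequence = sequence))
  })
}
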