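kit <- make_kit(6, 1, seed = 601)
scheme <- kit$scheme

test_that("scheme construction enforces label distinctness and lengths", {
  expect_length(default_scheme()$slots, 6)
  expect_error(slot_scheme("x", c("a", "b"), c("CAT", "CAT", "GGA")),
               class = "gatekit_config_error")
  expect_error(slot_scheme("x", c("a", "b"), c("CATA", "GTT", "GGA")),
               class = "gatekit_config_error")
  expect_error(slot_scheme("x", c("a", "b"), c("CAT", "GTT")),
               class = "gatekit_config_error")
})

test_that("parts classify to the span they were built for, over all spans", {
  spans <- gatekit:::all_spans(scheme)
  for (sp in spans[c(1, 4, 7, 11, 15, 18, 21)]) {
    clone <- make_entry_clone(scheme, sp, seed = 700 + nchar(sp), body_len = 50)
    cls <- classify_part(clone, scheme)
    expect_identical(cls$span, sp)
  }
  # fixture parts
  expect_identical(classify_part(kit$registry$molecules$p_FP, scheme)$span, "FP")
  expect_identical(classify_part(kit$registry$molecules$p_5arm_CT, scheme)$span,
                   "5arm-CT")
})

test_that("molecules releasing no span-matching insert are unassignable", {
  # the destination vector's backbone labels are the outer vector junctions,
  # which form no slot span
  expect_error(classify_part(kit$vector, scheme),
               class = "gatekit_unassignable_part")
  inert <- dna_molecule("noSites", strrep("ACGGT", 40), "circular")
  expect_error(classify_part(inert, scheme),
               class = "gatekit_unassignable_part")
})

test_that("a plasmid releasing two span-matching inserts is flagged", {
  # splice two entry inserts into one KanR backbone
  a <- make_entry_clone(scheme, "FP", seed = 801, id = "pa")
  b <- make_entry_clone(scheme, "NT", seed = 802, id = "pb")
  fa <- find_sites(a, "SapI")
  # insert cassette of a: from first cut to second (recognition sites inclusive)
  cassette <- function(m) {
    s <- find_sites(m, "SapI")
    rs <- sort(s$recognition_start)
    gatekit:::subseq0(m$sequence, rs[1], rs[2] + 7)
  }
  backbone <- gatekit:::scrub_sites(
    withr::with_seed(83, paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                               collapse = "")), c("SapI", "BsaI"))
  double <- dna_molecule("pdouble",
                         paste0(backbone, cassette(a), strrep("T", 20),
                                cassette(b)), "circular")
  expect_error(classify_part(double, scheme),
               class = "gatekit_multi_insert_part")
})

test_that("build_construct assembles tiling selections and orders features by slot", {
  sel <- c("5arm" = "p_5arm", CT = "p_CT", FP = "p_FP", SEC = "p_SEC",
           NT = "p_NT", "3arm" = "p_3arm")
  prod <- build_construct(kit$vector, sel, kit$registry, scheme)
  expect_equal(prod$diagnostics$residual_sites, 0L)
  f <- prod$molecule$features
  part_feats <- f[f$label %in% unname(sel), , drop = FALSE]
  expect_equal(nrow(part_feats), 6L)
  # rotate so the product starts at the 5arm part; slot order must follow
  ord <- part_feats$label[order(part_feats$start)]
  start_i <- which(ord == "p_5arm")
  expect_identical(ord[((seq_along(ord) + start_i - 2) %% 6) + 1],
                   unname(sel))
})

test_that("combined spans build from fewer parts and skip slots correctly", {
  sel <- c("5arm-CT" = "p_5arm_CT", FP = "p_FP", SEC = "p_SEC", NT = "p_NT",
           "3arm" = "p_3arm")
  prod <- build_construct(kit$vector, sel, kit$registry, scheme)
  expect_equal(nrow(prod$parts_used), 6L)  # backbone + 5 parts
  expect_true(verify_product(prod, "SapI")$clean)
})

test_that("selections with gaps or overlaps raise SlotCoverage errors", {
  expect_error(build_construct(kit$vector,
                               c("5arm" = "p_5arm", CT = "p_CT", FP = "p_FP",
                                 SEC = "p_SEC", "3arm" = "p_3arm"),
                               kit$registry, scheme),
               class = "gatekit_slot_coverage")
  expect_error(build_construct(kit$vector,
                               c("5arm-CT" = "p_5arm_CT", CT = "p_CT",
                                 FP = "p_FP", SEC = "p_SEC", NT = "p_NT",
                                 "3arm" = "p_3arm"),
                               kit$registry, scheme),
               class = "gatekit_slot_coverage")
})

test_that("build_construct writes annotated GenBank, plain FASTA and a JSON record", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "built")
  sel <- c("5arm-CT" = "p_5arm_CT", FP = "p_FP", SEC = "p_SEC", NT = "p_NT",
           "3arm" = "p_3arm")
  prod <- build_construct(kit$vector, sel, kit$registry, scheme,
                          out_prefix = prefix)
  gb <- read_record(paste0(prefix, ".gb"))
  fa <- read_record(paste0(prefix, ".fa"))
  expect_identical(gb$sequence, prod$molecule$sequence)
  expect_gt(nrow(gb$features), 0)
  expect_identical(fa$sequence, prod$molecule$sequence)
  expect_equal(nrow(fa$features), 0L)
  rec <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(rec$length_bp, nchar(prod$molecule$sequence))
})

test_that("validate_kit is clean on a pristine kit and names planted faults", {
  rep0 <- validate_kit(kit$registry, scheme, vector = kit$vector)
  expect_equal(nrow(rep0$findings), 0L)
  expect_true(all(diag(rep0$compatibility) == FALSE) ||
                is.logical(rep0$compatibility))

  # plant an internal BsaI site inside one part's insert body
  bad <- kit
  mol <- bad$registry$molecules$p_SEC
  cds <- mol$features[mol$features$label == "p_SEC", ]
  substr(mol$sequence, cds$start + 10, cds$start + 15) <- "GGTCTC"
  bad$registry$molecules$p_SEC <- mol
  rep1 <- validate_kit(bad$registry, scheme, vector = bad$vector)
  expect_true(any(rep1$findings$part_id == "p_SEC" &
                    rep1$findings$check == "internal_site"))
  expect_false(any(rep1$findings$part_id != "p_SEC"))

  # declare the FP part as an NT part: span mismatch
  swapped <- kit
  i <- which(swapped$registry$table$id == "p_FP")
  swapped$registry$table$slot_first[i] <- "NT"
  swapped$registry$table$slot_last[i] <- "NT"
  rep2 <- validate_kit(swapped$registry, scheme, vector = swapped$vector)
  expect_true(any(rep2$findings$part_id == "p_FP" &
                    rep2$findings$check == "span_mismatch"))
})

test_that("kits round-trip through disk: registry, scheme, vector, products", {
  dir <- withr::local_tempdir()
  write_kit(kit, dir)
  scheme2 <- read_scheme(file.path(dir, "scheme.tsv"))
  registry2 <- read_registry(file.path(dir, "registry.tsv"))
  vector2 <- read_record(file.path(dir, "vector.gb"))
  expect_identical(scheme2$junction_labels, scheme$junction_labels)
  rep <- validate_kit(registry2, scheme2, vector = vector2)
  expect_equal(nrow(rep$findings), 0L)
  sel <- c("5arm" = "p_5arm", CT = "p_CT", FP = "p_FP", SEC = "p_SEC",
           NT = "p_NT", "3arm" = "p_3arm")
  p1 <- build_construct(kit$vector, sel, kit$registry, scheme)
  p2 <- build_construct(vector2, sel, registry2, scheme2)
  expect_identical(p1$molecule$sequence, p2$molecule$sequence)
})
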