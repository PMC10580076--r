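kit6 <- make_kit(6, 1, seed = 101)
kit_parts <- kit6$registry$molecules[paste0("p_", kit6$scheme$slots)]

test_that("six entry clones co-assemble into exactly one site-free product", {
  prod <- assemble(kit6$vector, kit_parts, "SapI")
  expect_s3_class(prod, "assembly_product")
  expect_identical(prod$molecule$topology, "circular")
  expect_equal(nrow(prod$parts_used), 7L)  # backbone + 6 inserts
  expect_equal(prod$diagnostics$residual_sites, 0L)
  expect_length(prod$diagnostics$unused_inputs, 0)
  expect_equal(nrow(find_sites(prod$molecule, "SapI")), 0L)
  # the KanR entry backbones never enter; the AmpR destination backbone does
  markers <- prod$molecule$features$label[
    prod$molecule$features$kind == "selection_marker"]
  expect_identical(markers, "AmpR")
})

test_that("product length obeys the junction-counted-once formula", {
  for (n in c(2, 4, 6)) {
    kit <- make_kit(n, 1, seed = 300 + n)
    parts <- kit$registry$molecules[paste0("p_", kit$scheme$slots)]
    prod <- assemble(kit$vector, parts, "SapI")
    frs <- c(list(gatekit:::pick_backbone(digest(kit$vector, "SapI"),
                                          get_enzyme("SapI"), kit$vector$id)),
             lapply(parts, function(p) {
               fr <- Filter(function(f) gatekit:::usable_fragment(f, get_enzyme("SapI")),
                            digest(p, "SapI"))
               fr[[1]]
             }))
    oh <- get_enzyme("SapI")$overhang_len
    spans <- vapply(frs, function(f) nchar(gatekit:::fragment_full_span(f)),
                    integer(1))
    junctions <- length(frs)
    expect_equal(nchar(prod$molecule$sequence), sum(spans) - junctions * oh)
  }
})

test_that("closures agree with exhaustive ordering/orientation enumeration", {
  enz <- get_enzyme("SapI")
  for (n in c(2, 4, 6, 9)) {
    ss <- make_stress_set(n, seed = 400 + n)
    backbone <- gatekit:::pick_backbone(digest(ss$vector, enz), enz, ss$vector$id)
    pool <- lapply(ss$inserts, function(p) {
      Filter(function(f) gatekit:::usable_fragment(f, enz), digest(p, enz))[[1]]
    })
    got <- gatekit:::find_closures(backbone, pool)
    got_keys <- sort(vapply(got, function(cyc)
      oracle_canonical_circular(paste(vapply(cyc, `[[`, "", "sequence"),
                                      collapse = "")), character(1)))
    want <- oracle_closures(pkg_frag_to_oracle(backbone),
                            lapply(pool, pkg_frag_to_oracle))
    expect_identical(got_keys, want)
    expect_length(got, 1)
  }
})

test_that("a planted duplicate label is detected by both enumerator and oracle", {
  enz <- get_enzyme("SapI")
  ss <- make_stress_set(4, seed = 55)
  backbone <- gatekit:::pick_backbone(digest(ss$vector, enz), enz, ss$vector$id)
  pool <- lapply(ss$inserts, function(p) {
    Filter(function(f) gatekit:::usable_fragment(f, enz), digest(p, enz))[[1]]
  })
  # a different clone exposing insert 2's label pair creates a collision
  rival <- make_entry_clone(ss$scheme, "s2", seed = 56, id = "p_s2_rival",
                            body_len = 80)
  rival_frag <- Filter(function(f) gatekit:::usable_fragment(f, enz),
                       digest(rival, enz))[[1]]
  pool2 <- c(pool, list(rival_frag))
  got <- gatekit:::find_closures(backbone, pool2)
  want <- oracle_closures(pkg_frag_to_oracle(backbone),
                          lapply(pool2, pkg_frag_to_oracle))
  expect_equal(sort(vapply(got, function(cyc)
    oracle_canonical_circular(paste(vapply(cyc, `[[`, "", "sequence"),
                                    collapse = "")), character(1))), want)
  expect_length(got, 2)
  expect_error(assemble(ss$vector, c(ss$inserts, list(rival)), "SapI"),
               class = "gatekit_ambiguous_assembly")
})

test_that("a vector whose own labels match re-circularizes with zero parts", {
  rec <- "GCTCTTC"
  backbone <- gatekit:::scrub_sites(
    withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                              collapse = "")), c("SapI", "BsaI"))
  stuffer <- paste0("CAT", "A", revcomp_str(rec), strrep("AC", 15), rec, "A", "CAT")
  vec <- dna_molecule("selfclose", paste0(backbone, stuffer), "circular")
  prod <- assemble(vec, list(), "SapI")
  expect_equal(nrow(find_sites(prod$molecule, "SapI")), 0L)
  expect_equal(nchar(prod$molecule$sequence), 150 + 3)  # backbone + one junction
})

test_that("missing junctions and ambiguous assemblies raise typed errors", {
  expect_error(assemble(kit6$vector, kit_parts[-3], "SapI"),
               class = "gatekit_missing_junction")
  err <- tryCatch(assemble(kit6$vector, kit_parts[-3], "SapI"),
                  gatekit_missing_junction = function(e) e)
  expect_true(all(span_labels(kit6$scheme, "FP") %in% err$unmatched))

  two_fp <- make_entry_clone(kit6$scheme, "FP", seed = 77, id = "p_FP_dup")
  expect_error(assemble(kit6$vector, c(kit_parts, list(two_fp)), "SapI"),
               class = "gatekit_ambiguous_assembly")
})

test_that("an input contributing no fragment triggers an inert-input warning", {
  inert <- dna_molecule("inert", strrep("ACGGT", 30), "circular")
  expect_warning(
    prod <- assemble(kit6$vector, c(kit_parts, list(inert)), "SapI"),
    class = "gatekit_inert_input")
  expect_identical(prod$diagnostics$unused_inputs, "inert")
})

test_that("assembling the finished product with no parts returns it unchanged", {
  prod <- assemble(kit6$vector, kit_parts, "SapI")
  again <- assemble(prod, list(), "SapI")
  expect_identical(again$molecule$sequence, prod$molecule$sequence)
  expect_identical(again$molecule$topology, "circular")
})

test_that("verify_product flags residual sites and survives a GenBank round-trip", {
  prod <- assemble(kit6$vector, kit_parts, "SapI")
  expect_true(verify_product(prod, "SapI")$clean)

  bad <- prod$molecule
  substr(bad$sequence, 11, 17) <- "GCTCTTC"
  bad$features <- empty_features()
  expect_gte(verify_product(bad, "SapI")$residual_sites, 1)

  dir <- withr::local_tempdir()
  path <- file.path(dir, "prod.gb")
  write_record(prod$molecule, path)
  back <- read_record(path)
  expect_identical(verify_product(back, "SapI"), verify_product(prod, "SapI"))
})

test_that("multiplexing returns the Cartesian set, deterministically ordered", {
  kit <- make_kit(4, c(slot1 = 2, slot2 = 3, slot3 = 1, slot4 = 1), seed = 500)
  opts <- lapply(kit$scheme$slots, function(sl) {
    ids <- kit$registry$table$id[kit$registry$table$slot_first == sl &
                                   kit$registry$table$slot_last == sl]
    kit$registry$molecules[ids]
  })
  names(opts) <- kit$scheme$slots
  prods <- multiplex_assemble(kit$vector, opts, "SapI")
  expect_length(prods, 6)
  seqs <- vapply(prods, function(p) p$molecule$sequence, character(1))
  expect_equal(length(unique(seqs)), 6L)
  # deterministic: same call, same order
  prods2 <- multiplex_assemble(kit$vector, opts, "SapI")
  expect_identical(seqs, vapply(prods2, function(p) p$molecule$sequence, ""))
  # single options everywhere reduces to plain assemble
  singles <- lapply(opts, function(o) o[1])
  one <- multiplex_assemble(kit$vector, singles, "SapI")
  direct <- assemble(kit$vector, lapply(singles, `[[`, 1), "SapI")
  expect_identical(one[[1]]$molecule$sequence, direct$molecule$sequence)
})

test_that("slot options with differing labels are rejected", {
  kit <- make_kit(6, 1, seed = 101)
  opts <- list(FP = list(kit$registry$molecules$p_FP,
                         kit$registry$molecules$p_NT))
  expect_error(multiplex_assemble(kit$vector, opts, "SapI"),
               class = "gatekit_slot_heterogeneity")
})

test_that("self-complementary 4-nt overhangs are rejected unless overridden", {
  # BsaI-style chain built by hand: backbone with labels AATT (self-comp)
  rec <- "GGTCTC"
  backbone <- gatekit:::scrub_sites(
    withr::with_seed(10, paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                               collapse = "")), c("SapI", "BsaI"))
  stuffer <- paste0("AATT", "A", revcomp_str(rec), strrep("CA", 10), rec, "A", "AATT")
  vec <- dna_molecule("sc", paste0(backbone, stuffer), "circular")
  expect_error(assemble(vec, list(), "BsaI"),
               class = "gatekit_ambiguous_assembly")
  prod <- assemble(vec, list(), "BsaI", allow_self_complementary = TRUE)
  expect_equal(nchar(prod$molecule$sequence), 120 + 4)
})
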