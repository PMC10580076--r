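scheme <- make_kit(6, 1, seed = 901)$scheme

test_that("primer tails follow the stated anatomy and Tm rule", {
  ins <- make_random_insert(400, seed = 910)
  pp <- design_entry_primers(ins, "NT", scheme)
  expect_true(startsWith(pp$forward, paste0("AA", "GGTCTC", "A")))
  expect_true(startsWith(pp$reverse, paste0("AA", "GGTCTC", "A")))
  for (hom in c(pp$homology_fwd, pp$homology_rev)) {
    expect_gte(nchar(hom), 18)
    expect_lte(nchar(hom), 35)
    expect_true(primer_tm(hom) >= 55 || nchar(hom) == 35)
  }
  # homology regions anneal to the template exactly
  expect_true(grepl(pp$homology_fwd, ins$sequence, fixed = TRUE))
  expect_true(grepl(pp$homology_rev, ins$sequence, fixed = TRUE))

  dd <- design_direct_pcr_part(ins, "FP", scheme)
  expect_true(startsWith(dd$forward, paste0("AA", "GCTCTTC", "A")))
})

test_that("entry primers round-trip to a correctly classified entry clone", {
  for (sp in c("NT", "FP", "5arm-CT")) {
    ins <- make_random_insert(350, seed = 920 + nchar(sp))
    pp <- design_entry_primers(ins, sp, scheme)
    amp <- simulate_pcr(ins, pp)
    vec <- make_empty_entry_vector(scheme, sp, seed = 930 + nchar(sp))
    clone <- assemble(vec, list(amp), "BsaI", id = "clone")
    expect_equal(nrow(find_sites(clone$molecule, "BsaI")), 0L)
    expect_identical(classify_part(clone$molecule, scheme)$span, sp)
  }
})

test_that("inserts with internal sites are refused until domesticated", {
  dirty <- make_random_insert(400, seed = 940,
                              plant = list(list(enzyme = "SapI", pos = 100)))
  expect_error(design_entry_primers(dirty, "NT", scheme),
               class = "gatekit_domestication_required")
  expect_error(design_direct_pcr_part(dirty, "NT", scheme),
               class = "gatekit_domestication_required")
})

test_that("the same part delivered as plasmid or PCR product builds the same construct", {
  kit <- make_kit(6, 1, seed = 950)
  ins <- make_random_insert(300, seed = 951)
  pp <- design_entry_primers(ins, "NT", kit$scheme)
  clone <- assemble(make_empty_entry_vector(kit$scheme, "NT", seed = 952),
                    list(simulate_pcr(ins, pp)), "BsaI", id = "pNT_new")
  dp <- design_direct_pcr_part(ins, "NT", kit$scheme)
  amp <- simulate_pcr(ins, dp)
  parts <- kit$registry$molecules[paste0("p_", kit$scheme$slots)]
  parts$p_NT <- clone$molecule
  via_plasmid <- assemble(kit$vector, parts, "SapI")
  parts$p_NT <- amp
  via_pcr <- assemble(kit$vector, parts, "SapI")
  expect_identical(oracle_canonical_circular(via_plasmid$molecule$sequence),
                   oracle_canonical_circular(via_pcr$molecule$sequence))
})

test_that("PCR simulation demands exact, unique 3' anchors", {
  ins <- make_random_insert(300, seed = 960)
  pp <- design_entry_primers(ins, "SEC", scheme)
  mut <- ins
  # hit the 3'-terminal anchor of the reverse primer's homology footprint
  pos <- 300 - nchar(pp$homology_rev) + 6
  substr(mut$sequence, pos, pos) <- chartr("ACGT", "TGCA",
                                           substr(mut$sequence, pos, pos))
  expect_error(simulate_pcr(mut, pp), class = "gatekit_primer_error")
})

test_that("oligo duplexes compute labels from their extensions", {
  lab <- span_labels(scheme, "SEC")
  core <- "TTGGAGCCGGTGCTGGCGCAGGTAGCGGAGCAGGT"
  top <- paste0(lab["left"], core)
  bottom <- revcomp_str(paste0(core, lab["right"]))
  du <- oligo_duplex(top, bottom, 3, id = "lnk")
  expect_equal(du$left_end$label, unname(lab["left"]))
  expect_equal(du$right_end$label, unname(lab["right"]))
  expect_identical(du$source_kind, "oligo_duplex")

  kit <- make_kit(6, 1, seed = 901)
  lab2 <- span_labels(kit$scheme, "SEC")
  du2 <- oligo_duplex(paste0(lab2["left"], core),
                      revcomp_str(paste0(core, lab2["right"])), 3, id = "lnk2")
  parts <- kit$registry$molecules[paste0("p_", kit$scheme$slots)]
  parts$p_SEC <- du2
  prod <- assemble(kit$vector, parts, "SapI")
  expect_equal(prod$diagnostics$residual_sites, 0L)
  expect_true(grepl(core, prod$molecule$sequence, fixed = TRUE))
})

test_that("blunt duplexes cannot join a sticky assembly", {
  core <- "TTGGAGCCGGTGCTGGCGCAGGTAGCGGAGCAGG"
  blunt <- oligo_duplex(core, revcomp_str(core), 0)
  expect_identical(blunt$left_end$type, "blunt")
  kit <- make_kit(6, 1, seed = 901)
  parts <- kit$registry$molecules[paste0("p_", kit$scheme$slots)]
  parts$p_SEC <- blunt
  expect_error(suppressWarnings(assemble(kit$vector, parts, "SapI")),
               class = "gatekit_missing_junction")
})

test_that("duplex validation catches mismatches and bad extension lengths", {
  lab <- span_labels(scheme, "SEC")
  core <- "TTGGAGCCGGTGCTGGCGCAGGTAGCGGAGCAGGT"
  top <- paste0(lab["left"], core)
  bottom <- revcomp_str(paste0(core, lab["right"]))
  bad <- bottom
  substr(bad, 15, 15) <- chartr("ACGT", "TGCA", substr(bad, 15, 15))
  err <- tryCatch(oligo_duplex(top, bad, 3),
                  gatekit_anneal_error = function(e) e)
  expect_s3_class(err, "gatekit_anneal_error")
  expect_match(conditionMessage(err), "position")
  expect_error(oligo_duplex(top, bottom, 5), class = "gatekit_config_error")
  expect_error(oligo_duplex(top, paste0(bottom, "AC"), 3),
               class = "gatekit_config_error")
})

test_that("domestication removes one site with two fragments and silent lesions", {
  ins <- make_random_insert(420, seed = 970,
                            plant = list(list(enzyme = "SapI", pos = 150)))
  plan <- plan_domestication(ins, frame = 0)
  expect_equal(nrow(plan$fragments), 2L)
  expect_length(plan$primers, 2)
  expect_equal(nrow(plan$lesions), 1L)
  expect_identical(plan$lesions$synonymous, "yes")
  sim <- simulate_domestication(plan, ins)
  expect_true(sim$identical)
  expect_true(all(sim$site_counts == 0))
  expect_true(sim$translation_preserved)
  # the reconstruction differs from the input at exactly the lesion positions
  diffs <- which(strsplit(sim$reconstructed, "")[[1]] !=
                   strsplit(ins$sequence, "")[[1]])
  expect_identical(diffs - 1L, plan$lesions$position)
})

test_that("n internal sites yield n + 1 fragments", {
  ins <- make_random_insert(700, seed = 980,
                            plant = list(list(enzyme = "SapI", pos = 200),
                                         list(enzyme = "BsaI", pos = 450,
                                              strand = "-")))
  plan <- plan_domestication(ins)
  expect_equal(nrow(plan$fragments), 3L)
  expect_length(plan$primers, 3)
  sim <- simulate_domestication(plan, ins)
  expect_true(sim$identical)
  expect_true(all(sim$site_counts == 0))
})

test_that("degenerate domestication inputs are handled per flag", {
  clean <- make_random_insert(300, seed = 990)
  expect_error(plan_domestication(clean), class = "gatekit_parameter_error")
  noop <- plan_domestication(clean, allow_no_op = TRUE)
  expect_equal(nrow(noop$fragments), 1L)
  expect_identical(noop$target, clean$sequence)

  crowded <- make_random_insert(2000, seed = 991,
                                plant = lapply(c(200, 500, 800, 1100, 1400),
                                               function(p)
                                                 list(enzyme = "SapI", pos = p)))
  expect_error(plan_domestication(crowded), class = "gatekit_too_many_sites")

  circ <- dna_molecule("c", strrep("ACGT", 50), "circular")
  expect_error(plan_domestication(circ), class = "gatekit_topology_error")
})

test_that("a site with no synonymous escape raises NoSilentLesion", {
  # recognition ATGTGG spells Met-Trp in frame: neither codon has a synonym,
  # so no third-position substitution can silently remove a codon-aligned site
  mw <- enzyme_spec("MetTrpIIS", "ATGTGG", 1, 4)
  ins <- dna_molecule("hard", paste0(strrep("GGC", 10), "ATGTGG",
                                     strrep("GGC", 10)), "linear")
  expect_error(plan_domestication(ins, enzymes = list(mw), frame = 0),
               class = "gatekit_no_silent_lesion")
  # dropping the frame constraint permits a (non-silent) lesion
  plan <- plan_domestication(ins, enzymes = list(mw))
  expect_equal(nrow(plan$lesions), 1L)
  expect_identical(plan$lesions$synonymous, "unknown")
})

test_that("frame checking reports fusions, frameshifts and internal stops", {
  # in-frame fusion: two CDS features, contiguous codons, no internal stop
  m <- dna_molecule("fus", paste0("ATGGCTGCTGCT", "GGTGGAGGT", "TAA",
                                  strrep("C", 20)), "linear")
  m <- add_feature(m, "cds1", "CDS", 0, 12, "+")
  m <- add_feature(m, "cds2", "CDS", 12, 24, "+")
  rep <- check_frame(m)
  expect_true(rep$in_frame)
  expect_true(rep$clean)

  # junction inserting one extra nucleotide breaks the frame
  shift <- check_frame(m, cds_span = c(0, 25))
  expect_false(shift$in_frame)

  # internal stop in a linker
  m2 <- dna_molecule("stop", paste0("ATGGCT", "TAA", "GGTGGT", "TAA"), "linear")
  m2 <- add_feature(m2, "cds", "CDS", 0, 18, "+")
  rep2 <- check_frame(m2)
  expect_true(rep2$in_frame)
  expect_false(rep2$clean)
  expect_equal(rep2$internal_stops, 2L)
})
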