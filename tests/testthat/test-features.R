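test_that("bindsLigand is inclusive at the cutoff boundary", {
  s <- readPDB(fixture_basic())
  expect_true(bindsLigand(s, 1, "GOL"))    # nearest heavy atom at 4.9 A
  expect_false(bindsLigand(s, 2, "GOL"))   # 5.1 A
  expect_true(bindsLigand(s, 3, "GOL"))    # exactly 5.0 A
  expect_error(bindsLigand(s, 99, "GOL"), "not found")
})

test_that("bindsLigand is monotone in the cutoff", {
  s <- readPDB(fixture_basic())
  for (res in 1:3) {
    cuts <- c(2, 4, 5, 6, 10)
    hits <- vapply(cuts, function(cc) bindsLigand(s, res, "GOL", cutoff = cc),
                   logical(1))
    expect_true(all(diff(hits) >= 0))  # once TRUE, stays TRUE
  }
})

test_that("catalytic-domain membership has inclusive ends", {
  ranges <- data.frame(start = 30, end = 400)
  expect_true(inCatalyticDomain(ranges, 370))
  expect_false(inCatalyticDomain(ranges, 444))
  expect_true(inCatalyticDomain(ranges, 400))
  expect_true(inCatalyticDomain(ranges, 30))
  expect_false(inCatalyticDomain(ranges, 29))
  expect_error(inCatalyticDomain(data.frame(start = numeric(),
                                            end = numeric()), 1),
               "no catalytic ranges")
  expect_error(inCatalyticDomain(data.frame(start = c(1, 50),
                                            end = c(60, 90)), 10),
               "overlap")
})

test_that("contactProfile counts partner residue types and sums to degree", {
  syn <- makeStructure(12, "nested-loops")
  s <- syn$structure
  cm <- computeContacts(s)
  # residue 1 contacts residue 12 only; residue names cycle the 20 standard
  # types so residue 12 is LYS
  prof <- contactProfile(s, cm, 1)
  expect_equal(unname(prof["K"]), 1L)
  expect_equal(sum(prof), 1L)
  for (res in 1:12)
    expect_equal(sum(contactProfile(s, cm, res)),
                 contactCount(cm, res))
  iso <- contactProfile(s, cm, 2)
  expect_true(all(iso == 0L))
})

test_that("variant names parse with and without HGVS prefix", {
  v <- parseVariant(c("N370S", "p.L444P"))
  expect_equal(v$wt_aa, c("N", "L"))
  expect_equal(v$position, c(370L, 444L))
  expect_equal(v$mut_aa, c("S", "P"))
  expect_error(parseVariant("N370"), "cannot parse")
  expect_error(parseVariant("N370N"), "identical")
})

test_that("feature table passes printed features through verbatim", {
  tab <- buildFeatureTable(gaucherVariants())
  expect_equal(tab$variant, gaucherVariants()$variant)
  expect_equal(tab$ddg, gaucherVariants()$ddg)
  expect_equal(tab$n_contacts, gaucherVariants()$n_contacts)
  expect_equal(tab$p_inv, gaucherVariants()$p_inv)
  expect_equal(tab$catalytic_domain, gaucherVariants()$catalytic_domain)
  expect_false(any(tab$binds_ligand))
  # absent optional features are explicit NA, never zero
  expect_true(all(is.na(tab$ca_b_factor)))
  expect_true(all(is.na(tab$series)))
})

test_that("feature table computes structural features from a structure", {
  syn <- makeStructure(12, "hairpin", seed = 2)
  s <- syn$structure
  variants <- data.frame(
    variant = c("A1G", "R2G"),   # synthetic chain cycles ALA, ARG, ...
    ddg = c(1.0, -0.5))
  tab <- buildFeatureTable(variants, structure = s,
                           domain_config = data.frame(start = 1, end = 6))
  expect_equal(tab$n_contacts, c(1L, 1L))     # hairpin pairing
  expect_equal(tab$ca_b_factor, c(11, 12))    # b = 10 + resno %% 10
  expect_true(all(tab$catalytic_domain))
  expect_true(all(is.na(tab$binds_ligand)))   # no ligand selector given
  # wild-type identity is checked against the structure sequence
  expect_error(
    buildFeatureTable(data.frame(variant = "G1A", ddg = 0), structure = s),
    "structure has A")
})

test_that("feature table handles empty input and skip policy", {
  empty <- buildFeatureTable(data.frame(variant = character(),
                                        ddg = numeric()))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("variant", "ddg", "n_contacts", "p_inv",
                    "ca_b_factor") %in% names(empty)))
  syn <- makeStructure(8, "extended")
  v <- data.frame(variant = c("A1G", "A99G"), ddg = c(0, 0))
  expect_warning(
    tab <- buildFeatureTable(v, structure = syn$structure,
                             unresolved = "skip"),
    "A99G")
  expect_equal(tab$variant, "A1G")
  expect_error(buildFeatureTable(v, structure = syn$structure), "A99G")
})

test_that("feature table order follows input order", {
  g <- gaucherVariants()
  shuffled <- g[c(4, 1, 7, 2, 3, 6, 5), ]
  tab <- buildFeatureTable(shuffled)
  expect_equal(tab$variant, shuffled$variant)
  expect_equal(tab$ddg, shuffled$ddg)
})

test_that("PSSM reader consumes the log-odds matrix and ignores the footer", {
  m <- readPSSM(fixture_pssm(n_pos = 3))
  expect_equal(dim(m), c(3, 20))
  expect_equal(unname(m[1, "A"]), 101L)
  expect_equal(unname(m[3, "V"]), 320L)
  expect_equal(colnames(m)[1:4], c("A", "R", "N", "D"))
  expect_error(readPSSM(fixture_pssm(n_pos = 3, truncate_row = 2)),
               "line")
  bad <- tempfile()
  writeLines("not a pssm", bad)
  expect_error(readPSSM(bad), "header")
})

test_that("PSSM rows attach to variant positions in the feature table", {
  pssm <- readPSSM(fixture_pssm(n_pos = 5))
  v <- data.frame(variant = c("A2G", "C9G"), ddg = c(0, 0))
  tab <- buildFeatureTable(v, pssm = pssm)
  expect_equal(unname(tab$pssm_A[1]), 201L)
  expect_true(is.na(tab$pssm_A[2]))  # position beyond the PSSM
})
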