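write_gaucher_csv <- function(dir) {
  path <- file.path(dir, "variants.csv")
  g <- gaucherVariants()
  g$protein_id <- "glucocerebrosidase"
  write.csv(g, path, row.names = FALSE)
  path
}

test_that("feature stage passes a printed feature table through", {
  dir <- withr::local_tempdir()
  cfg <- list(variants = write_gaucher_csv(dir),
              outdir = file.path(dir, "out"))
  out <- runFeatures(cfg)
  expect_true(file.exists(out))
  tab <- attr(out, "table")
  expect_equal(tab$variant, gaucherVariants()$variant)
  expect_equal(tab$ddg, gaucherVariants()$ddg)
  expect_equal(tab$p_inv, gaucherVariants()$p_inv)
  prov <- jsonlite::read_json(file.path(dir, "out",
                                        "features-provenance.json"))
  expect_equal(prov$package, "chaperesp")
  expect_equal(prov$stage, "features")
})

test_that("feature stage computes from a synthetic structure end to end", {
  dir <- withr::local_tempdir()
  syn <- makeStructure(12, "hairpin", seed = 4)
  pdb <- file.path(dir, "toy.pdb")
  writeLines(syn$pdb_text, pdb)
  v <- data.frame(protein_id = "toy", variant = c("A1G", "R2G"),
                  ddg = c(0.5, 2.1))
  write.csv(v, file.path(dir, "variants.csv"), row.names = FALSE)
  cfg <- list(variants = file.path(dir, "variants.csv"), structure = pdb,
              preset = "methods",
              catalytic_ranges = list(c(1, 6)),
              outdir = file.path(dir, "out"))
  expect_warning(out <- runFeatures(cfg), "binds_ligand")
  tab <- attr(out, "table")
  expect_equal(tab$n_contacts, c(1L, 1L))
  expect_true(all(tab$catalytic_domain))
})

test_that("predict stage reproduces the published call set", {
  dir <- withr::local_tempdir()
  fcfg <- list(variants = write_gaucher_csv(dir),
               outdir = file.path(dir, "out"))
  features_csv <- runFeatures(fcfg)
  pcfg <- list(features = features_csv, outdir = file.path(dir, "out"))
  out <- runPredict(pcfg)
  preds <- attr(out, "table")
  expect_equal(preds$responsive,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(preds$p1, c(0.60, 0.28, 0.60, 0.34, 0.28, 0.60, 0.60))
  # schema errors name the missing columns
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(ddg = 1), bad, row.names = FALSE)
  expect_error(runPredict(list(features = bad, outdir = dir)),
               "binds_ligand.*n_contacts.*p_inv")
})

test_that("empty feature tables predict to empty output", {
  dir <- withr::local_tempdir()
  empty <- buildFeatureTable(data.frame(variant = character(),
                                        ddg = numeric()))
  f <- file.path(dir, "empty.csv")
  write.csv(empty, f, row.names = FALSE)
  out <- runPredict(list(features = f, outdir = dir))
  expect_equal(nrow(attr(out, "table")), 0)
})

test_that("workflow outputs are byte-identical across reruns", {
  dir <- withr::local_tempdir()
  vcsv <- write_gaucher_csv(dir)
  run_once <- function(sub) {
    od <- file.path(dir, sub)
    f <- runFeatures(list(variants = vcsv, outdir = od))
    runPredict(list(features = f, outdir = od))
    od
  }
  d1 <- run_once("r1")
  d2 <- run_once("r2")
  for (f in c("features.csv", "predictions.csv", "kinetics.csv")) {
    p1 <- file.path(d1, f); p2 <- file.path(d2, f)
    if (!file.exists(p1)) next
    expect_identical(readLines(p1), readLines(p2))
  }
  expect_identical(readLines(file.path(d1, "predictions.csv")),
                   readLines(file.path(d2, "predictions.csv")))
})

test_that("kinetics stage writes the four tidy curves", {
  dir <- withr::local_tempdir()
  out <- runKinetics(list(ddg_min = 0, ddg_max = 2, step = 0.25,
                          outdir = dir))
  tab <- attr(out, "table")
  expect_equal(nrow(tab), 4 * 9)
  expect_setequal(unique(tab$mode), c("unfolding", "folding"))
  expect_setequal(unique(tab$chaperone), c(TRUE, FALSE))
  for (m in c("unfolding", "folding")) {
    on <- tab$dEdt[tab$mode == m & tab$chaperone]
    off <- tab$dEdt[tab$mode == m & !tab$chaperone]
    expect_true(all(on >= off))
  }
  # coarse and fine grids agree at shared points
  fine <- runKinetics(list(ddg_min = 0, ddg_max = 2, step = 0.125,
                           outdir = file.path(dir, "fine")))
  ftab <- attr(fine, "table")
  shared <- merge(tab, ftab, by = c("ddg", "mode", "chaperone"))
  expect_equal(shared$dEdt.x, shared$dEdt.y, tolerance = 1e-12)
})

test_that("YAML configs load with relative path resolution", {
  dir <- withr::local_tempdir()
  write_gaucher_csv(dir)
  cfgfile <- file.path(dir, "run.yaml")
  writeLines(c("variants: variants.csv",
               paste0("outdir: ", file.path(dir, "out"))), cfgfile)
  cfg <- loadConfig(cfgfile)
  expect_true(file.exists(cfg$variants))
  out <- runFeatures(cfg)
  expect_true(file.exists(out))
  expect_error(loadConfig(file.path(dir, "missing.yaml")), "no such config")
})
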