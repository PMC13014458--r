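test_that("PFIc is the sum of logP and the aromatic ring count", {
  expect_equal(computePFIC(3.0, 3), 6.0)
  expect_equal(computePFIC(0.0, 0), 0.0)
  expect_equal(computePFIC(-1.25, 2), 0.75)
  expect_error(computePFIC(NaN, 1), "finite")
  expect_error(computePFIC(Inf, 1), "finite")
  expect_error(computePFIC(1, -1), "non-negative")
  # strictly increasing in each argument
  for (i in 1:20) {
    lp <- rnorm(1); nr <- sample(0:5, 1)
    expect_lt(computePFIC(lp, nr), computePFIC(lp + 0.1, nr))
    expect_lt(computePFIC(lp, nr), computePFIC(lp, nr + 1))
  }
})

test_that("property filters are inclusive and name every violated filter", {
  pool <- sixRecordFilterFixture()
  res <- applyFilters(pool, filterSpec())
  # hand enumeration: f1 sits exactly on every boundary (600, 3 rings,
  # PFIc = 5 + 3 = 8, 6 HBD, 11 HBA) and survives; f3 exceeds only the
  # weight budget; f5 exceeds only the HBD limit
  expect_identical(poolIds(res$survivors), c("f1", "f2", "f4", "f6"))
  expect_identical(res$rejections$id, c("f3", "f5"))
  expect_identical(res$rejections$reasons[[1]], "molecular_weight")
  expect_identical(res$rejections$reasons[[2]], "hbd")
  # partition: survivors + rejected = pool
  expect_equal(poolSize(res$survivors) + nrow(res$rejections), poolSize(pool))
  # idempotence
  res2 <- applyFilters(res$survivors, filterSpec())
  expect_identical(poolIds(res2$survivors), poolIds(res$survivors))
  expect_equal(nrow(res2$rejections), 0L)
})

test_that("a record missing a property is rejected with reason missing_property", {
  props <- data.frame(mol_weight = c(300, NA), n_aromatic_rings = c(1, 1),
                      logp = c(1, 1), n_hbd = c(1, 1), n_hba = c(2, 2))
  pool <- moleculePool(c("a", "b"), properties = props)
  res <- applyFilters(pool)
  expect_identical(poolIds(res$survivors), "a")
  expect_true("missing_property" %in% res$rejections$reasons[[1]])
})

test_that("filter rejection respects each threshold individually", {
  base <- list(mol_weight = 400, n_aromatic_rings = 2, logp = 1,
               n_hbd = 2, n_hba = 4)
  violations <- list(
    molecular_weight = c(mol_weight = 601),
    aromatic_rings = c(n_aromatic_rings = 4),
    pfic = c(logp = 7),            # PFIc = 7 + 2 = 9 > 8
    hbd = c(n_hbd = 7),
    hba = c(n_hba = 12))
  for (nm in names(violations)) {
    props <- base
    props[names(violations[[nm]])] <- violations[[nm]]
    pool <- moleculePool("x", properties = as.data.frame(props))
    res <- applyFilters(pool)
    expect_identical(res$rejections$reasons[[1]], nm)
  }
})

test_that("toy library enumeration yields the combinatorial count", {
  spec <- toyLibrarySpec(r1Fragments = c("C", "O", "N"),
                         r2Fragments = c("F", "Cl", "C", "OC"))
  lib <- enumerateToyLibrary(spec)
  expect_equal(poolSize(lib), 3 + 4 + 12)
  expect_false(anyDuplicated(poolIds(lib)) > 0)

  one <- enumerateToyLibrary(toyLibrarySpec(r1Fragments = "C",
                                            r2Fragments = "O",
                                            modes = "mono_r1"))
  expect_equal(poolSize(one), 1L)

  di <- enumerateToyLibrary(toyLibrarySpec(
    r1Fragments = c("C", "O", "N", "F", "Cl"),
    r2Fragments = c("C", "O", "N", "F", "Cl"), modes = "di"))
  expect_equal(poolSize(di), 25L)
  expect_equal(anyDuplicated(poolIds(di)), 0L)

  # closed-form count for arbitrary mode subsets
  for (modes in list("mono_r1", c("mono_r1", "di"),
                     c("mono_r2", "di"), c("mono_r1", "mono_r2", "di"))) {
    lib <- enumerateToyLibrary(toyLibrarySpec(
      r1Fragments = c("C", "O"), r2Fragments = c("N", "F", "Cl"),
      modes = modes))
    expected <- ("mono_r1" %in% modes) * 2 + ("mono_r2" %in% modes) * 3 +
      ("di" %in% modes) * 6
    expect_equal(poolSize(lib), expected)
  }
})

test_that("toy library ids are deterministic across enumerations", {
  spec <- toyLibrarySpec(r1Fragments = c("C", "O"), r2Fragments = "N")
  expect_identical(poolIds(enumerateToyLibrary(spec)),
                   poolIds(enumerateToyLibrary(spec)))
})

test_that("synthetic descriptor provider passes vectors through and imputes", {
  pool <- randomPool(5)
  out <- computeDescriptors(pool, "synthetic")
  expect_identical(descriptorMatrix(out$pool), descriptorMatrix(pool))
  expect_equal(nrow(out$imputed), 0L)

  d <- descriptorMatrix(pool)
  d[2, 3] <- NaN
  pool@descriptors <- d
  out <- computeDescriptors(pool, "synthetic")
  expect_equal(unname(descriptorMatrix(out$pool)[2, 3]), 0)
  expect_identical(out$imputed$id, poolIds(pool)[2])
  expect_true(all(is.finite(descriptorMatrix(out$pool))))
})

test_that("structure-based descriptors count aromatic rings and agree for duplicates", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  pool <- moleculePool(c("benzene", "lib1", "dup_of_lib1", "broken"),
                       smiles = c("c1ccccc1",
                                  "Cc1noc(C)c1-c1ccccc1",
                                  "Cc1noc(C)c1-c1ccccc1",
                                  "not_a_smiles(("))
  out <- computeDescriptors(pool, "openbabel")
  expect_identical(out$invalid, "broken")
  d <- descriptorMatrix(out$pool)
  expect_equal(unname(d["benzene", "n_aromatic_rings"]), 1)
  expect_equal(unname(d["lib1", "n_aromatic_rings"]), 2)
  expect_equal(d["lib1", ], d["dup_of_lib1", ])
  pr <- moleculeProperties(out$pool)
  expect_true(all(pr$mol_weight > 0))
})
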