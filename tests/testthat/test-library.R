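test_that("ugi condensation conserves mass and checks roles", {
  rg <- read_reagents()
  am <- rg[rg$name == "benzylamine", ]
  al <- rg[rg$name == "cyclohexanecarboxaldehyde", ]
  ac <- rg[rg$name == "Boc-glycine", ]
  iso <- rg[rg$name == "cyclohexyl isocyanide", ]
  p <- ugi_condense(am, al, ac, iso)
  expect_identical(format(p$formula), "C28H43N3O4")
  expect_equal(p$M, 485.3254, tolerance = 1e-4)
  # four reagents -> product + water
  expect_equal(p$M + monoisotopic_mass("H2O"),
               am$mass + al$mass + ac$mass + iso$mass, tolerance = 1e-9)
  expect_error(ugi_condense(al, am, ac, iso), "role")

  tiny <- ugi_condense(reagent("methylamine", "amine", "CH5N"),
                       reagent("formaldehyde", "aldehyde", "CH2O"),
                       reagent("formic acid", "acid", "CH2O2"),
                       reagent("hydrogen isocyanide", "isocyanide", "CHN"))
  expect_identical(format(tiny$formula), "C4H8N2O2")
})

test_that("library enumeration is the full Cartesian product in frozen order", {
  lib <- full_library()
  expect_s3_class(lib, "ugi_library")
  expect_identical(nrow(lib), 1500L)
  expect_identical(lib$index, seq_len(1500L))
  # amine slowest, isocyanide fastest
  rg <- read_reagents()
  iso_names <- rg$name[rg$role == "isocyanide"]
  expect_identical(lib$isocyanide[1:5], iso_names)
  expect_identical(length(unique(lib$amine[1:300])), 1L)
  # deterministic: re-running yields identical order
  expect_identical(enumerate_library(rg)$formula, lib$formula)
  # bijection between quadruples and indices
  key <- paste(lib$amine, lib$aldehyde, lib$acid, lib$isocyanide)
  expect_identical(anyDuplicated(key), 0L)
  expect_error(enumerate_library(rg[rg$role != "amine", ]), "empty")
})

test_that("every enumerated product obeys mass conservation", {
  lib <- small_library()
  rg <- attr(lib, "reagents")
  expect_identical(nrow(lib), 24L)
  masses <- rg$mass[match(lib$amine, rg$name)] +
    rg$mass[match(lib$aldehyde, rg$name)] +
    rg$mass[match(lib$acid, rg$name)] +
    rg$mass[match(lib$isocyanide, rg$name)]
  expect_equal(lib$M + 18.010565, masses, tolerance = 1e-6)
})

test_that("larger reagent sets scale multiplicatively", {
  rg <- read_reagents()
  # duplicate reagents to reach 10 per role (names made unique)
  aug <- do.call(rbind, lapply(split(rg, rg$role), function(g) {
    g2 <- g[rep(seq_len(nrow(g)), length.out = 10L), ]
    g2$name <- paste0(g2$name, "#", seq_len(10L))
    g2
  }))
  lib10 <- enumerate_library(aug)
  expect_identical(nrow(lib10), 10000L)
})

test_that("mass collisions equal the brute-force pairwise oracle", {
  lib <- small_library()
  tol <- 5
  groups <- mass_collisions(lib, tol)
  # oracle: connected components of all-pairs ppm graph via repeated merging
  n <- nrow(lib)
  adj <- abs(outer(lib$M, lib$M, "-")) /
    outer(lib$M, lib$M, function(a, b) (a + b) / 2) * 1e6 <= tol
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      link <- which(adj[i, ])
      new <- min(comp[link])
      if (any(comp[link] != new)) { comp[link] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  oracle <- unname(Filter(function(g) length(g) >= 2, split(seq_len(n), comp)))
  normalize <- function(gs) {
    gs <- lapply(gs, function(g) sort(as.integer(g)))
    gs[order(vapply(gs, `[`, integer(1), 1))]
  }
  expect_identical(normalize(groups), normalize(oracle))
  # the two packaged acid isomers collide in every shared context
  expect_true(length(groups) >= 1)
  expect_identical(mass_collisions(lib[0, ], 5), list())
  ident <- lib[c(1, 1), ]
  expect_identical(mass_collisions(ident, 5), list(c(1L, 2L)))
})

test_that("library export includes adduct columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_library(small_library(), path)
  df <- read.csv(path)
  expect_true(all(c("mz_H", "mz_Na", "mz_K") %in% names(df)))
  expect_equal(df$mz_Na - df$M, rep(22.989221, nrow(df)), tolerance = 1e-5)
})
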