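test_that("ring_series enforces its invariants", {
  s <- rs(c(1.2, 0, 1.4), last_year = 2000)
  expect_s3_class(s, "ring_series")
  expect_equal(length(s), 3L)
  expect_equal(first_year(s), 1998L)
  expect_error(rs(numeric(0)), "at least one")
  expect_error(rs(c(1, -0.5)), "non-negative")
  expect_error(rs(c(1, NA)), "finite")
})

test_that("RWL values are stored in 0.01 mm units and converted on read", {
  f <- withr::local_tempfile()
  writeLines("SER1        1  150   150   150   999", f)
  out <- read_rwl(f)
  expect_length(out, 1L)
  expect_equal(out[[1]]$widths, c(1.50, 1.50, 1.50))
  expect_equal(out[[1]]$resolution_mm, 0.01)
})

test_that("a decade-break series anchors its years from the decade labels", {
  f <- withr::local_tempfile()
  writeLines(c("FIX1    1998   150   160",
               "FIX1    2000   170   999"), f)
  out <- read_rwl(f)
  expect_equal(out[[1]]$widths, c(1.5, 1.6, 1.7))
  expect_equal(out[[1]]$last_year, 2000L)
  expect_equal(first_year(out[[1]]), 1998L)
})

test_that("write_rwl/read_rwl round-trips widths exactly at both resolutions", {
  set.seed(7)
  series <- lapply(1:4, function(k) {
    w <- round(runif(sample(30:260, 1), 0.02, 8), 2)
    w[sample(length(w), 3)] <- 0                     # wedge rings
    rs(w, tree_id = paste0("T", k), radius_id = sprintf("SER%d", k),
       last_year = 2015)
  })
  f <- withr::local_tempfile()
  write_rwl(series, f)
  back <- read_rwl(f)
  for (k in seq_along(series)) {
    expect_equal(back[[k]]$widths, series[[k]]$widths)
    expect_equal(back[[k]]$last_year, series[[k]]$last_year)
  }
  # 0.001 mm dialect with -9999 terminator
  s3 <- rs(c(0.123, 4.567, 0.001), radius_id = "FINE", last_year = 3)
  write_rwl(s3, f, resolution_mm = 0.001)
  expect_equal(read_rwl(f)[[1]]$widths, s3$widths)
})

test_that("a lifetime-scale series spans the decade count the format dictates", {
  w <- rep(1.5, 255)
  s <- rs(w, radius_id = "OLD1", last_year = 2015)
  f <- withr::local_tempfile()
  write_rwl(s, f)
  lines <- readLines(f)
  # values (255) + terminator occupy consecutive decades from first_year
  fy <- 2015 - 255 + 1
  years_spanned <- seq(fy, length.out = 256)
  expect_equal(length(lines), length(unique(years_spanned %/% 10)))
  expect_match(lines[length(lines)], "999$")
})

test_that("parsing never silently drops rings", {
  cfg <- default_cohort_config(seed = 11)
  cfg$species_blocks <- cfg$species_blocks[1]
  cfg$species_blocks[[1]]$n_trees <- 3
  cohort <- simulate_cohort(cfg)
  radii <- unlist(lapply(cohort$trees, `[[`, "radii"), recursive = FALSE)
  f <- withr::local_tempfile()
  write_rwl(radii, f)
  # per line: series id, decade year, then data values; terminators are one
  # per series.  Non-terminator value count must equal total ring count.
  per_line <- vapply(strsplit(trimws(readLines(f)), "\\s+"), length, integer(1))
  n_values <- sum(per_line - 2L)
  expect_equal(n_values - length(radii),
               sum(vapply(radii, length, integer(1))))
  # and the reader recovers every one of them
  expect_equal(sum(vapply(read_rwl(f), length, integer(1))),
               sum(vapply(radii, length, integer(1))))
})

test_that("malformed RWL input fails loudly", {
  f <- withr::local_tempfile()
  writeLines(c("BAD1    1990   100   110",
               "BAD1    2010   120   999"), f)   # 2000 decade missing
  expect_error(read_rwl(f), "line 2: malformed decade")
  writeLines("NEG1    1990   100   -50   999", f)
  expect_error(read_rwl(f), "negative width")
})

test_that("write_rwl rejects widths that collide with the terminator field", {
  s <- rs(c(1.0, 9.99), radius_id = "CLSH")
  f <- withr::local_tempfile()
  expect_error(write_rwl(s, f), "999 terminator")
  write_rwl(s, f, resolution_mm = 0.001)         # fine in the 0.001 dialect
  expect_equal(read_rwl(f)[[1]]$widths, s$widths)
})

test_that("empty collection writes an empty file", {
  f <- withr::local_tempfile()
  write_rwl(list(), f)
  expect_identical(readLines(f), character(0))
})

test_that("long-form table round-trips and is order-invariant", {
  series <- list(rs(c(1, 2, 3), tree_id = "A", radius_id = "r1", last_year = 2002),
                 rs(c(0.5, 0.7), tree_id = "A", radius_id = "r2", last_year = 2002),
                 rs(4:6 / 10, tree_id = "B", radius_id = "r1", last_year = 2002))
  f <- withr::local_tempfile()
  write_series_table(series, f)
  back <- read_series_table(f)
  expect_length(back, 3L)
  expect_equal(back[[1]]$widths, c(1, 2, 3))
  expect_equal(back[[1]]$last_year, 2002L)
  # shuffle the rows; parsed series must be identical
  df <- read.csv(f)
  set.seed(1)
  write.csv(df[sample(nrow(df)), ], f, row.names = FALSE, quote = FALSE)
  expect_equal(read_series_table(f), back)
})

test_that("table reader rejects gaps and duplicate years", {
  f <- withr::local_tempfile()
  writeLines(c("tree_id,species,radius_id,year,width_mm",
               "A,sp,r1,2000,1.0", "A,sp,r1,2002,1.2"), f)
  expect_error(read_series_table(f), "missing year.*2001")
  writeLines(c("tree_id,species,radius_id,year,width_mm",
               "A,sp,r1,2000,1.0", "A,sp,r1,2000,1.2"), f)
  expect_error(read_series_table(f), "duplicate year")
})

test_that("tree_record looks up species wood densities and validates", {
  s <- rs(c(1, 2))
  tr <- tree_record("T1", "C.odorata", list(s))
  expect_equal(tr$wood_density, 0.38)
  expect_equal(tree_record("T1", "H.courbaril", list(s))$wood_density, 0.77)
  expect_equal(tree_record("T1", "G.glabra", list(s))$wood_density, 0.72)
  expect_error(tree_record("T1", "unknown_sp", list(s)), "no default wood density")
  expect_error(tree_record("T1", "C.odorata", list(s), carbon_fraction = 1.2),
               "carbon_fraction")
  expect_error(tree_record("T2", "C.odorata", list(s)), "tree's id")
})
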