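# Shared fixtures: everything is generated in code, nothing on disk.

# Minimal bridge_dataset from a plain data frame (fills derivable columns).
fake_dataset <- function(df) {
  if (is.null(df$ringA)) df$ringA <- df$proximal
  if (is.null(df$ringB)) df$ringB <- df$distal
  if (is.null(df$bridge)) df$bridge <- "A"
  if (is.null(df$diff)) df$diff <- df$ea - df$sm
  if (is.null(df$has_pt_minimum)) df$has_pt_minimum <- TRUE
  structure(df, class = c("bridge_dataset", "data.frame"))
}

# Small admissible truth table with round values (distinct from the
# packaged one) for round-trip tests.
toy_truth <- function(e_dist = numeric(0), s_dist = numeric(0)) {
  subs <- c("Br", "NH2", "NO2")
  key13 <- paste0(subs, ":13"); key24 <- paste0(subs, ":24")
  key1 <- paste0(subs, ":1"); key4 <- paste0(subs, ":4")
  increment_table(
    e_sub = setNames(c(-0.5, 0.25, -1.0, 0.8, -0.3, 0.1), c(key13, key24)),
    s_sub = setNames(c(-0.4, 0.2, -0.9, 0.5, -0.2, 0.3), c(key13, key24)),
    e_ster = setNames(c(-1.2, 0.4, -0.7, 0.6, -0.1, -0.9), c(key1, key4)),
    s_ster = setNames(c(-0.8, 0.3, -0.5, 0.2, -0.15, -0.6), c(key1, key4)),
    e_dist = e_dist, s_dist = s_dist,
    source = "toy")
}

default_bases <- function(groups = c("para", "meta")) {
  base_parameters(groups, e_base = 12, s_base = 10)
}

# Compare two increment tables key by key.
expect_tables_equal <- function(fitted, truth, tol = 1e-9) {
  for (comp in c("e_sub", "s_sub", "e_ster", "s_ster")) {
    keys <- names(truth[[comp]])
    expect_setequal(names(fitted[[comp]]), keys)
    expect_equal(fitted[[comp]][keys], truth[[comp]][keys],
                 tolerance = tol, ignore_attr = TRUE)
  }
}

# n uniform draws in [-0.5, 0.5] under a local seed.
with_seed_vector <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  runif(n, -0.5, 0.5)
}

write_profile_file <- function(distances, energies, path = tempfile(fileext = ".csv"),
                               header = TRUE) {
  lines <- paste(distances, energies, sep = ",")
  if (header) lines <- c("distance,energy", lines)
  writeLines(lines, path)
  path
}
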