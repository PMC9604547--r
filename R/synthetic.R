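# Evaluate code with a temporary RNG state so generators are
# reproducible without disturbing the caller's random stream.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Shape of a generated double-well scan profile
#'
#' Geometry of the synthetic O-H scan grid and the placement of its
#' stationary points.  The defaults reproduce the scan protocol the
#' package targets -- a start near the optimised O-H distance elongated
#' by 20 increments of 0.05 Angstrom (21 points) -- with the barrier and
#' the proton-transferred minimum on interior grid nodes.
#'
#' @param r_start first O-H distance, Angstrom (default 0.95).
#' @param step grid increment, Angstrom (default 0.05).
#' @param n_steps number of increments (default 20, i.e. 21 points).
#' @param barrier_index,pt_min_index 0-based grid indices of the barrier
#'   top and the PT minimum; must satisfy
#'   `0 < barrier_index < pt_min_index < n_steps`.
#' @param tail_rise energy rise from the PT minimum to the last point,
#'   kcal/mol, > 0.
#' @return An object of class `profile_shape`.
#' @export
profile_shape <- function(r_start = 0.95, step = 0.05, n_steps = 20,
                          barrier_index = 7, pt_min_index = 14,
                          tail_rise = 2) {
  stopifnot(step > 0, n_steps >= 4, tail_rise > 0)
  if (!(0 < barrier_index && barrier_index < pt_min_index &&
        pt_min_index < n_steps)) {
    stop("need 0 < barrier_index < pt_min_index < n_steps", call. = FALSE)
  }
  structure(list(r_start = r_start, step = step, n_steps = as.integer(n_steps),
                 barrier_index = as.integer(barrier_index),
                 pt_min_index = as.integer(pt_min_index),
                 tail_rise = tail_rise),
            class = "profile_shape")
}

#' Generate a double-well scan profile with known parameters
#'
#' Builds the energy curve by smooth cubic interpolation through the
#' control points (start, 0), (barrier, `ea`), (PT minimum, `sm`) and
#' (end, `sm + tail_rise`), with zero slope at the three stationary
#' points, so each segment is strictly monotone and the extrema sit
#' exactly on grid nodes.  Gaussian noise (`noise_sd`, kcal/mol) is
#' added to non-control points only: at `noise_sd = 0` the round trip
#' through [extract_bridge_parameters()] recovers `(ea, sm)` exactly,
#' and with noise the control energies stay exact while the curve
#' between them degrades gracefully.
#'
#' @param ea activation energy, kcal/mol; must satisfy
#'   `ea >= sm >= 0`.  `ea == sm` gives a flat-topped (degenerate) well.
#' @param sm second minimum, kcal/mol.
#' @param shape a [profile_shape()].
#' @param noise_sd Gaussian noise SD on non-control energies, kcal/mol.
#' @param seed optional integer for reproducible noise.
#' @return A [scan_profile()].
#' @examples
#' p <- generate_profile(12, 10)
#' extract_bridge_parameters(p)
#' @export
generate_profile <- function(ea, sm, shape = profile_shape(),
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(shape, "profile_shape"), noise_sd >= 0)
  if (sm > ea) stop("second minimum above barrier (sm > ea)", call. = FALSE)
  if (sm < 0) stop("second minimum must be >= 0", call. = FALSE)
  n <- shape$n_steps
  ctrl_idx <- c(0L, shape$barrier_index, shape$pt_min_index, n)
  ctrl_val <- c(0, ea, sm, sm + shape$tail_rise)
  energies <- numeric(n + 1)
  smoothstep <- function(t) t * t * (3 - 2 * t)
  for (s in seq_len(3)) {
    i0 <- ctrl_idx[s]; i1 <- ctrl_idx[s + 1]
    idx <- i0:i1
    t <- (idx - i0) / (i1 - i0)
    energies[idx + 1] <- ctrl_val[s] + (ctrl_val[s + 1] - ctrl_val[s]) *
      smoothstep(t)
  }
  if (noise_sd > 0) {
    free <- setdiff(0:n, ctrl_idx)
    energies[free + 1] <- energies[free + 1] +
      with_preserved_seed(seed, stats::rnorm(length(free), 0, noise_sd))
  }
  distances <- shape$r_start + shape$step * (0:n)
  scan_profile(distances, energies, reference = "none")
}

#' Configuration of the synthetic substitution-grid generator
#'
#' Bundles the ground truth and sampling conditions for
#' [generate_dataset()]: an increment table taken as truth, base
#' parameters per group, the (group, proximal, distal) view grid to
#' enumerate, Gaussian noise, optional pairwise interaction terms that
#' deliberately break additivity (mimicking, e.g., the spring-like
#' O...N repulsion of doubly bridge-adjacent nitro substitution), and an
#' optional inflation factor for ortho-group distal effects emulating
#' cross-bridge coupling.
#'
#' @param truth ground-truth `increment_table` (default the packaged
#'   empirical table).
#' @param bases base parameters per group; default `EBC = 12`,
#'   `SBC = 10` kcal/mol for every group -- deliberately arbitrary
#'   double-well parents chosen to keep `ea >= sm >= 0` over the grid.
#' @param groups groups to enumerate (default `c("para", "meta")`).
#' @param proximal,distal pattern labels spanning the view grid
#'   (defaults: all 13 each).
#' @param noise_sd Gaussian noise SD on generated EA and SM, kcal/mol.
#' @param interaction_terms optional named numeric, kcal/mol, keyed
#'   `"<proximal>|<distal>"` (e.g. `"NO2,1|NH2,4"`), added to EA of the
#'   matching view.
#' @param sm_interaction_terms same for SM.
#' @param ortho_distal_factor multiplier on distal increments in the
#'   ortho group (default 1, i.e. off; ~1.6 mimics the stronger
#'   cross-bridge coupling there).
#' @param seed integer; fixed seed implies byte-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(truth = empirical_increments(),
                             bases = NULL,
                             groups = c("para", "meta"),
                             proximal = all_patterns(),
                             distal = all_patterns(),
                             noise_sd = 0,
                             interaction_terms = NULL,
                             sm_interaction_terms = NULL,
                             ortho_distal_factor = 1,
                             seed = 1L) {
  stopifnot(inherits(truth, "increment_table"), noise_sd >= 0)
  groups <- match.arg(groups, GROUPS, several.ok = TRUE)
  if (is.null(bases)) {
    bases <- base_parameters(groups, e_base = 12, s_base = 10)
  }
  structure(list(truth = truth, bases = bases, groups = groups,
                 proximal = proximal, distal = distal,
                 noise_sd = noise_sd,
                 interaction_terms = interaction_terms,
                 sm_interaction_terms = sm_interaction_terms,
                 ortho_distal_factor = ortho_distal_factor,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Noiseless additive evaluation of one view against a truth table.
additive_value <- function(truth, base, prox_label, dist_label,
                           dist_factor = 1) {
  prox <- as_pattern(prox_label)
  dist <- as_pattern(dist_label)
  e_terms <- c(base$e_base, 0, 0, 0)  # base, sub, ster, dist
  s_terms <- c(base$s_base, 0, 0, 0)
  if (!is.na(prox$substituent)) {
    key <- sub_pair_key(prox$substituent, prox$position)
    if (!key %in% names(truth$e_sub) || !key %in% names(truth$s_sub)) {
      stop("truth table missing substituent entry '", key, "'",
           call. = FALSE)
    }
    e_terms[2] <- truth$e_sub[[key]]
    s_terms[2] <- truth$s_sub[[key]]
    if (prox$position %in% c(1L, 4L)) {
      skey <- ster_key(prox$substituent, prox$position)
      if (!skey %in% names(truth$e_ster) || !skey %in% names(truth$s_ster)) {
        stop("truth table missing steric entry '", skey, "'", call. = FALSE)
      }
      e_terms[3] <- truth$e_ster[[skey]]
      s_terms[3] <- truth$s_ster[[skey]]
    }
  }
  if (!is.na(dist$substituent)) {
    dkey <- format_pattern_label(dist)
    if (dkey %in% names(truth$e_dist)) {
      e_terms[4] <- dist_factor * truth$e_dist[[dkey]]
    }
    if (dkey %in% names(truth$s_dist)) {
      s_terms[4] <- dist_factor * truth$s_dist[[dkey]]
    }
  }
  # summed the same way predict_bridge sums its itemised components, so
  # noiseless generation and prediction agree bit-exactly
  c(ea = sum(e_terms), sm = sum(s_terms))
}

#' Generate a synthetic substitution-grid dataset
#'
#' Literal evaluation of the additive model over the configured view
#' grid: for each (group, proximal, distal) view,
#' `EA = EBC + IE-SUB + IE-STER + IE-DIST (+ interaction) + noise` and
#' the second-minimum analogue.  With `noise_sd = 0` and no interaction
#' terms every record satisfies the model exactly, which makes the
#' generate-fit round trip the package's central oracle.
#'
#' @param config a [synthetic_config()].
#' @return A `bridge_dataset` (bridge `"A"` views; `ringA` = proximal,
#'   `ringB` = distal), with the configuration attached as attribute
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- enumerate_views(config$groups, config$proximal, config$distal)
  n <- nrow(grid)
  ea <- sm <- numeric(n)
  for (i in seq_len(n)) {
    b <- base_row(config$bases, grid$group[i])
    f <- if (grid$group[i] == "ortho") config$ortho_distal_factor else 1
    v <- additive_value(config$truth, b, grid$proximal[i], grid$distal[i], f)
    key <- paste0(grid$proximal[i], "|", grid$distal[i])
    inter <- config$interaction_terms
    if (!is.null(inter) && key %in% names(inter)) v[["ea"]] <- v[["ea"]] + inter[[key]]
    s_inter <- config$sm_interaction_terms
    if (!is.null(s_inter) && key %in% names(s_inter)) v[["sm"]] <- v[["sm"]] + s_inter[[key]]
    ea[i] <- v[["ea"]]; sm[i] <- v[["sm"]]
  }
  if (config$noise_sd > 0) {
    eps <- with_preserved_seed(config$seed,
                               stats::rnorm(2 * n, 0, config$noise_sd))
    ea <- ea + eps[seq_len(n)]
    sm <- sm + eps[n + seq_len(n)]
  }
  out <- data.frame(group = grid$group,
                    ringA = grid$proximal, ringB = grid$distal,
                    bridge = "A",
                    proximal = grid$proximal, distal = grid$distal,
                    ea = ea, sm = sm, diff = ea - sm,
                    has_pt_minimum = TRUE,
                    stringsAsFactors = FALSE)
  out <- as_bridge_dataset(out)
  attr(out, "config") <- config
  out
}

#' Write a complete fixture suite of profiles and manifests
#'
#' Materialises the full para+meta mono-substitution view grid
#' (13 proximal x 13 distal patterns per group) from the packaged
#' empirical increment table with base parameters `EBC = 12`,
#' `SBC = 10` kcal/mol, as scan-profile CSV files plus a manifest, in
#' two variants: `noiseless/` (exact round trips) and `noisy/`
#' (Gaussian noise of `noise_sd` on non-control profile points).
#' Profiles carry no pre-extracted parameters, so loading the manifest
#' exercises the extraction path.  Reruns with the same seed produce
#' byte-identical files.
#'
#' @param out_dir directory to populate (created if needed).
#' @param noise_sd profile noise SD for the noisy variant, kcal/mol.
#' @param seed integer seed.
#' @param groups groups to include.
#' @return Named character vector with the `noiseless` and `noisy`
#'   manifest paths.
#' @export
make_fixture_suite <- function(out_dir, noise_sd = 0.1, seed = 42,
                               groups = c("para", "meta")) {
  config <- synthetic_config(groups = groups, seed = seed)
  dataset <- generate_dataset(config)
  shape <- profile_shape()
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  manifests <- c(noiseless = NA_character_, noisy = NA_character_)
  for (variant in names(manifests)) {
    vdir <- file.path(out_dir, variant)
    dir.create(vdir, showWarnings = FALSE)
    sd <- if (variant == "noisy") noise_sd else 0
    paths <- character(nrow(dataset))
    for (i in seq_len(nrow(dataset))) {
      fname <- sprintf("%s_%s__%s.csv", dataset$group[i],
                       gsub(",", "-", dataset$proximal[i]),
                       gsub(",", "-", dataset$distal[i]))
      profile <- generate_profile(dataset$ea[i], dataset$sm[i], shape,
                                  noise_sd = sd, seed = seed + i)
      utils::write.csv(data.frame(distance = profile$distances,
                                  energy = profile$energies),
                       file.path(vdir, fname), row.names = FALSE,
                       quote = FALSE)
      paths[i] <- file.path(variant, fname)
    }
    manifest <- data.frame(group = dataset$group, ringA = dataset$ringA,
                           ringB = dataset$ringB, bridge = dataset$bridge,
                           profile_path = paths, stringsAsFactors = FALSE)
    mpath <- file.path(out_dir, paste0("manifest_", variant, ".csv"))
    utils::write.csv(manifest, mpath, row.names = FALSE)
    manifests[variant] <- mpath
  }
  manifests
}
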