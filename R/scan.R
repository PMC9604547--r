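# Hartree -> kcal/mol
HARTREE_KCAL <- 627.509

#' Scan profile of a hydrogen-bridge proton-transfer coordinate
#'
#' Container for one relaxed O-H scan: strictly increasing O-H distances
#' (Angstrom) with the energy (kcal/mol) at each point, referenced so
#' that the first point -- the optimised molecular form the scan starts
#' from -- sits at 0.
#'
#' @param distances numeric vector of O-H separations, strictly
#'   increasing, Angstrom.
#' @param energies numeric vector of energies, kcal/mol, same length.
#' @param reference either `"first"` (shift so the first point is 0, the
#'   default) or `"none"` (energies taken as given).
#' @return An object of class `scan_profile` with fields `distances`,
#'   `energies`, `n_points`.
#' @export
scan_profile <- function(distances, energies, reference = c("first", "none")) {
  reference <- match.arg(reference)
  distances <- as.numeric(distances)
  energies <- as.numeric(energies)
  if (length(distances) != length(energies)) {
    stop("distances and energies must have the same length", call. = FALSE)
  }
  if (anyNA(distances) || anyNA(energies)) {
    stop("profile contains non-numeric or missing values", call. = FALSE)
  }
  if (length(distances) < 4) {
    stop("profile needs at least 4 points", call. = FALSE)
  }
  if (any(diff(distances) <= 0)) {
    stop("distances must be strictly increasing", call. = FALSE)
  }
  if (reference == "first") energies <- energies - energies[1]
  structure(list(distances = distances, energies = energies,
                 n_points = length(distances)),
            class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  step <- diff(x$distances)
  cat("<scan profile> ", x$n_points, " points, ",
      sprintf("%.3f", x$distances[1]), " to ",
      sprintf("%.3f", x$distances[x$n_points]), " Angstrom",
      if (max(step) - min(step) < 1e-9)
        paste0(" (uniform step ", sprintf("%.3f", step[1]), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read a scan profile from a two-column table
#'
#' Accepts CSV or whitespace-delimited text with two numeric columns
#' (O-H distance in Angstrom, energy), with or without a header line.
#' Energies given in hartree are converted to kcal/mol
#' (1 hartree = 627.509 kcal/mol); all profiles are then shifted so the
#' first point's energy is 0.
#'
#' @param path file to read.
#' @param energy_unit `"kcal_mol"` (default) or `"hartree"`.
#' @return A [scan_profile()].
#' @export
read_profile <- function(path, energy_unit = c("kcal_mol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("profile file is empty: ", path, call. = FALSE)
  parse_line <- function(l) strsplit(l, "[,;[:space:]]+")[[1]]
  first <- suppressWarnings(as.numeric(parse_line(lines[1])))
  if (anyNA(first)) lines <- lines[-1]  # header line
  cells <- lapply(lines, parse_line)
  if (any(lengths(cells) < 2)) {
    stop("each profile row needs a distance and an energy", call. = FALSE)
  }
  num <- suppressWarnings(vapply(cells, function(x) as.numeric(x[1:2]),
                                 numeric(2)))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 2, any))[1]
    stop("non-numeric cell in profile row ", bad, call. = FALSE)
  }
  if (ncol(num) < 5) {
    stop("profile has fewer than 5 points", call. = FALSE)
  }
  energies <- num[2, ]
  if (energy_unit == "hartree") energies <- energies * HARTREE_KCAL
  scan_profile(num[1, ], energies)
}

# Run-length extrema on the discrete grid.  A run of equal energies is a
# local maximum (minimum) when both neighbouring runs are lower (higher);
# the leftmost point of a plateau is the candidate extremum.
locate_extrema <- function(energies) {
  r <- rle(energies)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(r$values)
  maxima <- integer(0); minima <- integer(0); plateaus <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      v <- r$values[j]
      if (v > r$values[j - 1] && v > r$values[j + 1]) maxima <- c(maxima, starts[j])
      if (v < r$values[j - 1] && v < r$values[j + 1]) minima <- c(minima, starts[j])
      if (r$lengths[j] >= 2 && v > r$values[j - 1] && v < r$values[j + 1]) {
        plateaus <- c(plateaus, starts[j])  # flat shoulder on a rise
      }
    }
  }
  list(maxima = maxima, minima = minima, plateaus = plateaus)
}

parabolic_vertex <- function(x, y) {
  # vertex of the parabola through three points
  d2 <- (y[3] - 2 * y[2] + y[1])
  if (d2 == 0) return(c(x = x[2], y = y[2]))
  h <- x[2] - x[1]
  dx <- 0.5 * h * (y[1] - y[3]) / d2
  c(x = x[2] + dx, y = y[2] - 0.25 * (y[1] - y[3]) * dx / h)
}

#' Extract bridge parameters from a scan profile
#'
#' Locates the proton-transfer barrier and the second (proton-
#' transferred, PT) minimum on the discrete grid and reports the three
#' bridge parameters, all referenced to the energy at the first point
#' (the optimised molecular form):
#' * `activation_energy` (EA) -- energy of the first interior local
#'   maximum after the start;
#' * `second_minimum` (SM) -- energy of the first local minimum after
#'   that barrier;
#' * `difference` -- `EA - SM`, always derived, never stored
#'   independently.
#'
#' A point is a local extremum when strictly above/below both
#' neighbours; for a plateau of equal energies the leftmost point is the
#' candidate.  A profile with no interior barrier-then-minimum structure
#' (for instance strictly monotone) has `has_pt_minimum = FALSE` and
#' `NA` parameters.  A flat-topped profile where barrier and PT well
#' merge is returned with `difference = 0` and flag `"degenerate"`.  A
#' PT minimum below the molecular form (negative SM) is permitted and
#' flagged `"pt_below_molecular"` with a warning; the reference stays at
#' the first point.
#'
#' @param profile a [scan_profile()].
#' @param refine `"none"` (default; grid resolution, matching the 0.05
#'   Angstrom scan step) or `"parabolic"` (three-point parabolic
#'   refinement of barrier and minimum energies).
#' @return An object of class `bridge_parameters`: fields
#'   `activation_energy`, `second_minimum`, `difference`,
#'   `has_pt_minimum`, `flags` (character), `barrier_index`,
#'   `pt_min_index`, `n_extra_extrema`.
#' @export
extract_bridge_parameters <- function(profile, refine = c("none", "parabolic")) {
  refine <- match.arg(refine)
  stopifnot(inherits(profile, "scan_profile"))
  e <- profile$energies
  ext <- locate_extrema(e)
  flags <- character(0)

  barrier <- ext$maxima[ext$maxima > 1][1]
  pt_min <- NA_integer_
  if (!is.na(barrier)) {
    pt_min <- ext$minima[ext$minima > barrier][1]
  }

  degenerate <- FALSE
  if (is.na(barrier) || is.na(pt_min)) {
    # flat-topped well: a rising plateau stands in for barrier + PT well
    if (length(ext$plateaus)) {
      barrier <- pt_min <- ext$plateaus[1]
      degenerate <- TRUE
      flags <- c(flags, "degenerate")
    } else {
      return(structure(list(activation_energy = NA_real_,
                            second_minimum = NA_real_,
                            difference = NA_real_,
                            has_pt_minimum = FALSE,
                            flags = "no_pt_minimum",
                            barrier_index = NA_integer_,
                            pt_min_index = NA_integer_,
                            n_extra_extrema = 0L),
                       class = "bridge_parameters"))
    }
  }

  ea <- e[barrier]
  sm <- e[pt_min]
  if (refine == "parabolic" && !degenerate &&
      barrier > 1 && barrier < profile$n_points &&
      pt_min > 1 && pt_min < profile$n_points) {
    ea <- parabolic_vertex(profile$distances[(barrier - 1):(barrier + 1)],
                           e[(barrier - 1):(barrier + 1)])[["y"]]
    sm <- parabolic_vertex(profile$distances[(pt_min - 1):(pt_min + 1)],
                           e[(pt_min - 1):(pt_min + 1)])[["y"]]
  }

  if (sm < 0) {
    flags <- c(flags, "pt_below_molecular")
    warning("PT-form minimum lies below the molecular-form reference ",
            "(second minimum = ", signif(sm, 4), " kcal/mol)", call. = FALSE)
  }
  extra <- sum(ext$maxima > barrier) + sum(ext$minima > pt_min)
  if (extra > 0) flags <- c(flags, "extra_extrema")

  structure(list(activation_energy = ea,
                 second_minimum = sm,
                 difference = ea - sm,
                 has_pt_minimum = TRUE,
                 flags = flags,
                 barrier_index = as.integer(barrier),
                 pt_min_index = as.integer(pt_min),
                 n_extra_extrema = as.integer(extra)),
            class = "bridge_parameters")
}

#' @export
print.bridge_parameters <- function(x, ...) {
  if (!x$has_pt_minimum) {
    cat("<bridge parameters> no proton-transfer minimum\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<bridge parameters> EA = %.3f, SM = %.3f, ",
                     "difference = %.3f kcal/mol\n"),
              x$activation_energy, x$second_minimum, x$difference))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
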