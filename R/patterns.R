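#' @keywords internal
"_PACKAGE"

# Enumerated sets for the substitution grid.  Positions are ring-local
# labels 1-4: 1 is adjacent to the C1-N linkage, 4 adjacent to the C4-O
# linkage; no renumbering is ever applied.
SUBSTITUENTS <- c("Br", "NH2", "NO2")
POSITIONS <- 1:4
GROUPS <- c("ortho", "meta", "para")

#' Substitution pattern for one outer ring
#'
#' A pattern is a (substituent, position) pair describing a single outer
#' ring of a tri-ring Schiff base: one of `Br`, `NH2`, `NO2` at a ring
#' position 1-4, or the unsubstituted ring (both fields `NA`).  A ring
#' carries at most one substituent.
#'
#' @param substituent `"Br"`, `"NH2"`, `"NO2"`, or `NA`/`"None"` for an
#'   unsubstituted ring.
#' @param position integer position 1-4, or `NA`/`"None"` when
#'   unsubstituted.  A substituent without a position (or vice versa) is
#'   an error.
#' @return An object of class `hb_pattern` with fields `substituent` and
#'   `position`.
#' @examples
#' substitution_pattern("Br", 3)
#' substitution_pattern()          # unsubstituted ring
#' @export
substitution_pattern <- function(substituent = NA, position = NA) {
  if (is.character(substituent) && length(substituent) == 1 &&
      !is.na(substituent) && toupper(substituent) == "NONE") {
    substituent <- NA
  }
  if ((is.character(position) || is.factor(position)) && length(position) == 1 &&
      !is.na(position) && toupper(as.character(position)) == "NONE") {
    position <- NA
  }
  sub_na <- is.na(substituent)
  pos_na <- is.na(position)
  if (sub_na != pos_na) {
    stop("a substituent must come with a position (and vice versa); got ",
         "substituent = ", if (sub_na) "None" else substituent,
         ", position = ", if (pos_na) "None" else position, call. = FALSE)
  }
  if (!sub_na) {
    substituent <- canonical_substituent(substituent)
    position <- suppressWarnings(as.integer(as.character(position)))
    if (is.na(position) || !position %in% POSITIONS) {
      stop("position must be one of 1, 2, 3, 4", call. = FALSE)
    }
  } else {
    substituent <- NA_character_
    position <- NA_integer_
  }
  structure(list(substituent = substituent, position = position),
            class = "hb_pattern")
}

canonical_substituent <- function(x) {
  x <- gsub("\\s", "", as.character(x))
  hit <- match(toupper(x), toupper(SUBSTITUENTS))
  if (is.na(hit)) {
    stop("unknown substituent '", x, "'; expected one of ",
         paste(SUBSTITUENTS, collapse = ", "), " or None", call. = FALSE)
  }
  SUBSTITUENTS[hit]
}

#' @export
print.hb_pattern <- function(x, ...) {
  cat("<substitution pattern> ", format_pattern_label(x), "\n", sep = "")
  invisible(x)
}

is_unsubstituted <- function(pattern) {
  if (inherits(pattern, "hb_pattern")) return(is.na(pattern$substituent))
  lab <- canonical_pattern_label(pattern)
  lab == "None,None"
}

#' Parse a single-ring substitution label
#'
#' Labels follow the "substituent, position" notation, e.g. `"Br, 3"` or
#' `"NO2,1"`; an unsubstituted ring is written `"None, None"` (the bare
#' token `"None"` is also accepted).  Parsing is whitespace-insensitive
#' and case-normalising.
#'
#' @param label character scalar.
#' @return An `hb_pattern`.
#' @seealso [format_pattern_label()] for the inverse.
#' @examples
#' parse_pattern_label("Br, 3")
#' parse_pattern_label("None, None")
#' @export
parse_pattern_label <- function(label) {
  if (!is.character(label) || length(label) != 1 || is.na(label)) {
    stop("label must be a single character string", call. = FALSE)
  }
  raw <- gsub("\\s", "", label)
  if (toupper(raw) %in% c("NONE", "NONE,NONE")) {
    return(substitution_pattern())
  }
  parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
    stop("cannot parse pattern label '", label,
         "'; expected 'substituent, position' or 'None, None'",
         call. = FALSE)
  }
  substitution_pattern(parts[1], parts[2])
}

#' Format a substitution pattern as its canonical ASCII label
#'
#' @param pattern an `hb_pattern` (or a label coercible to one).
#' @return Canonical label such as `"Br,3"` or `"None,None"`.
#' @export
format_pattern_label <- function(pattern) {
  pattern <- as_pattern(pattern)
  if (is.na(pattern$substituent)) return("None,None")
  paste0(pattern$substituent, ",", pattern$position)
}

as_pattern <- function(x) {
  if (inherits(x, "hb_pattern")) return(x)
  parse_pattern_label(x)
}

# Canonical string form used as key throughout the package.
canonical_pattern_label <- function(x) format_pattern_label(as_pattern(x))

#' Enumerate all single-ring substitution patterns
#'
#' @param include_unsubstituted put the unsubstituted pattern first
#'   (default `TRUE`), giving the 13 canonical labels; otherwise the 12
#'   substituted ones.  Ordering is substituent `Br`, `NH2`, `NO2`, each
#'   over positions 1-4.
#' @return Character vector of canonical labels.
#' @export
all_patterns <- function(include_unsubstituted = TRUE) {
  subs <- as.vector(t(outer(SUBSTITUENTS, POSITIONS, paste, sep = ",")))
  if (include_unsubstituted) c("None,None", subs) else subs
}

#' Compound specification
#'
#' One physical compound: a parent group (`ortho`, `meta` or `para`,
#' named for the relation of the two bridges on the centre ring) plus a
#' substitution pattern for each outer ring, at most one substituent per
#' ring.
#'
#' @param group `"ortho"`, `"meta"` or `"para"`.
#' @param ringA,ringB `hb_pattern` objects or labels.
#' @return An object of class `hb_compound`.
#' @examples
#' compound_spec("meta", "None,None", "Br,3")
#' @export
compound_spec <- function(group, ringA = "None,None", ringB = "None,None") {
  group <- match.arg(as.character(group), GROUPS)
  structure(list(group = group,
                 ringA = as_pattern(ringA),
                 ringB = as_pattern(ringB)),
            class = "hb_compound")
}

#' @export
print.hb_compound <- function(x, ...) {
  cat("<compound> ", x$group, ": ", format_compound_label(x), "\n", sep = "")
  invisible(x)
}

#' Parse / format a two-ring compound label
#'
#' The two ring patterns are joined "A, X--B, Y"; both the em-dash
#' separator of the original notation and the ASCII `--` are accepted on
#' input, and the ASCII form is emitted on output.
#'
#' @param label character scalar such as `"Br,3--NO2,1"`.
#' @param group parent group for the resulting spec.
#' @return `parse_compound_label()` returns an `hb_compound`;
#'   `format_compound_label()` a character scalar.
#' @export
parse_compound_label <- function(label, group = "meta") {
  raw <- gsub("—", "--", label)  # em-dash dialect
  parts <- strsplit(raw, "--", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("cannot split compound label '", label, "' into two ring patterns",
         call. = FALSE)
  }
  compound_spec(group, parse_pattern_label(parts[1]),
                parse_pattern_label(parts[2]))
}

#' @rdname parse_compound_label
#' @param spec an `hb_compound`.
#' @export
format_compound_label <- function(spec) {
  paste0(format_pattern_label(spec$ringA), "--",
         format_pattern_label(spec$ringB))
}

#' Derive the two bridge views of a compound
#'
#' The parent compounds carry two symmetrically located hydrogen bridges,
#' so every compound is scanned twice -- once per bridge -- and each scan
#' sees one outer ring as proximal (adjacent to the scanned bridge) and
#' the other as distal.  Scanning bridge A makes ring A proximal and ring
#' B distal; bridge B the reverse.
#'
#' @param spec an `hb_compound`.
#' @return A list of two `hb_view` objects (bridges `"A"` and `"B"`),
#'   each with fields `group`, `bridge`, `proximal`, `distal`.
#' @examples
#' v <- bridge_views(compound_spec("meta", "None,None", "Br,3"))
#' v$A$distal    # Br,3 seen from bridge A
#' v$B$proximal  # Br,3 seen from bridge B
#' @export
bridge_views <- function(spec) {
  stopifnot(inherits(spec, "hb_compound"))
  mk <- function(bridge, proximal, distal) {
    structure(list(group = spec$group, bridge = bridge,
                   proximal = proximal, distal = distal,
                   spec = spec),
              class = "hb_view")
  }
  list(A = mk("A", spec$ringA, spec$ringB),
       B = mk("B", spec$ringB, spec$ringA))
}

#' @export
print.hb_view <- function(x, ...) {
  cat("<bridge view> ", x$group, " bridge ", x$bridge,
      ": proximal ", format_pattern_label(x$proximal),
      ", distal ", format_pattern_label(x$distal), "\n", sep = "")
  invisible(x)
}

#' Enumerate the full proximal x distal view grid
#'
#' @param groups parent groups to enumerate.
#' @param proximal,distal canonical pattern labels for each axis; the
#'   defaults give the full 13 x 13 mono-substitution view grid per
#'   group.
#' @return A data frame with columns `group`, `proximal`, `distal`.
#' @export
enumerate_views <- function(groups = c("para", "meta"),
                            proximal = all_patterns(),
                            distal = all_patterns()) {
  groups <- match.arg(groups, GROUPS, several.ok = TRUE)
  out <- expand.grid(distal = distal, proximal = proximal, group = groups,
                     stringsAsFactors = FALSE)
  out <- out[, c("group", "proximal", "distal")]
  rownames(out) <- NULL
  out
}

# ---- dataset manifests -----------------------------------------------------

MANIFEST_COLUMNS <- c("group", "ringA", "ringB", "bridge", "profile_path",
                      "ea", "sm")

#' Load a compound dataset from a manifest
#'
#' A manifest lists one record per scanned bridge of a compound, with
#' columns `group`, `ringA`, `ringB`, `bridge` and either extracted
#' bridge parameters (`ea`, `sm`, always kcal/mol) or a `profile_path`
#' pointing at a two-column scan profile (resolved relative to the
#' manifest).  Records missing `ea`/`sm` have them extracted from the
#' profile on load.  CSV (header required) and JSON (array of objects,
#' same field names) are accepted.  Extra numeric columns (for example a
#' distal-ring charge sum) are carried through as auxiliary scalars.
#'
#' @param manifest path to a CSV or JSON manifest.
#' @return A `bridge_dataset`: a data frame with one row per record and
#'   columns `group`, `ringA`, `ringB`, `bridge`, `proximal`, `distal`,
#'   `ea`, `sm`, `diff`, `has_pt_minimum`, plus any auxiliary columns.
#' @seealso [write_dataset()]
#' @export
load_dataset <- function(manifest) {
  if (!file.exists(manifest)) {
    stop("manifest file not found: ", manifest, call. = FALSE)
  }
  if (grepl("\\.json$", manifest, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(manifest, simplifyDataFrame = TRUE)
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  required <- c("group", "ringA", "ringB", "bridge")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(raw)) stop("manifest contains no records", call. = FALSE)
  base_dir <- dirname(normalizePath(manifest))

  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    rows[[i]] <- tryCatch(
      manifest_row(raw[i, , drop = FALSE], base_dir),
      error = function(e) {
        stop("malformed manifest row ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  key <- paste(out$group, out$ringA, out$ringB, out$bridge)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate record for (group, ringA, ringB, bridge) = (",
         gsub(" ", ", ", dup), ")", call. = FALSE)
  }
  as_bridge_dataset(out)
}

manifest_row <- function(row, base_dir) {
  spec <- compound_spec(row$group, as_pattern(row$ringA),
                        as_pattern(row$ringB))
  bridge <- toupper(as.character(row$bridge))
  if (!bridge %in% c("A", "B")) {
    stop("bridge must be 'A' or 'B', got '", row$bridge, "'")
  }
  view <- bridge_views(spec)[[bridge]]
  ea <- if ("ea" %in% names(row)) suppressWarnings(as.numeric(row$ea)) else NA_real_
  sm <- if ("sm" %in% names(row)) suppressWarnings(as.numeric(row$sm)) else NA_real_
  has_pt <- TRUE
  if (is.na(ea) || is.na(sm)) {
    path <- if ("profile_path" %in% names(row)) as.character(row$profile_path) else NA
    if (is.na(path) || !nzchar(path)) {
      stop("record has neither extracted parameters nor a profile_path")
    }
    if (!file.exists(path)) path <- file.path(base_dir, path)
    profile <- read_profile(path)
    pars <- extract_bridge_parameters(profile)
    ea <- pars$activation_energy
    sm <- pars$second_minimum
    has_pt <- pars$has_pt_minimum
  }
  out <- data.frame(group = spec$group,
                    ringA = format_pattern_label(spec$ringA),
                    ringB = format_pattern_label(spec$ringB),
                    bridge = bridge,
                    proximal = format_pattern_label(view$proximal),
                    distal = format_pattern_label(view$distal),
                    ea = ea, sm = sm, diff = ea - sm,
                    has_pt_minimum = has_pt,
                    stringsAsFactors = FALSE)
  # carry auxiliary numeric columns through untouched
  aux <- setdiff(names(row), c(MANIFEST_COLUMNS, names(out)))
  for (a in aux) out[[a]] <- suppressWarnings(as.numeric(row[[a]]))
  out
}

as_bridge_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  class(df) <- unique(c("bridge_dataset", class(df)))
  df
}

#' Write a compound dataset back to a CSV manifest
#'
#' Emits the ASCII label dialect and extracted energies in kcal/mol, so
#' `load_dataset()` on the result reproduces the records.
#'
#' @param dataset a `bridge_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "bridge_dataset"))
  keep <- c("group", "ringA", "ringB", "bridge", "ea", "sm")
  aux <- setdiff(names(dataset),
                 c(keep, "proximal", "distal", "diff", "has_pt_minimum",
                   "profile_path"))
  utils::write.csv(dataset[, c(keep, aux), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.bridge_dataset <- function(x, ...) {
  cat("<bridge dataset> ", nrow(x), " records, groups: ",
      paste(sort(unique(x$group)), collapse = ", "), "\n", sep = "")
  NextMethod()
}
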