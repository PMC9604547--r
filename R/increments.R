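# Keys: substituent increments ("sub") are shared within the position
# pairs 1/3 and 2/4 and keyed "Br:13", "Br:24", ...; steric increments
# ("ster") exist only for the bridge-adjacent positions 1 and 4 and are
# keyed "Br:1", "Br:4", ...; distal increments are keyed by the full
# distal pattern label ("Br,1", ...).
sub_pair_key <- function(substituent, position) {
  pair <- if (position %in% c(1L, 3L)) "13" else "24"
  paste0(substituent, ":", pair)
}
ster_key <- function(substituent, position) paste0(substituent, ":", position)

#' Increment table of the composite substituent effect
#'
#' Holds the empirical increments of the additive model
#' `EA = EBC + IE-SUB + IE-STER + IE-DIST` and its second-minimum
#' analogue `SM = SBC + IS-SUB + IS-STER (+ IS-DIST)`:
#' * `e_sub`, `s_sub` -- classical (resonance/induction) substituent
#'   increments, one value per substituent and position pair 1/3 or 2/4,
#'   keyed `"Br:13"`, `"NO2:24"`, ...;
#' * `e_ster`, `s_ster` -- proximity ("steric") increments for the
#'   bridge-adjacent positions 1 and 4 only, keyed `"Br:1"`, ...;
#' * `e_dist`, `s_dist` -- optional distal-ring increments keyed by the
#'   distal pattern label (`"Br,3"`, ...).
#'
#' All values are kcal/mol.  The unsubstituted pattern contributes 0 to
#' every component and is never stored.
#'
#' @param e_sub,s_sub,e_ster,s_ster,e_dist,s_dist named numeric vectors
#'   (possibly empty) using the keys above.
#' @param source free-text provenance tag (e.g. `"literature"`,
#'   `"fitted"`).
#' @return An object of class `increment_table`.
#' @seealso [empirical_increments()], [fit_increments()],
#'   [read_increments()]
#' @export
increment_table <- function(e_sub = numeric(0), s_sub = numeric(0),
                            e_ster = numeric(0), s_ster = numeric(0),
                            e_dist = numeric(0), s_dist = numeric(0),
                            source = NULL) {
  comp <- list(e_sub = e_sub, s_sub = s_sub, e_ster = e_ster,
               s_ster = s_ster, e_dist = e_dist, s_dist = s_dist)
  for (nm in names(comp)) {
    v <- comp[[nm]]
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
      stop("component '", nm, "' must be a named numeric vector",
           call. = FALSE)
    }
    comp[[nm]] <- as.numeric(stats::setNames(v, names(v)))
    names(comp[[nm]]) <- names(v)
  }
  pair_keys <- unique(c(names(comp$e_sub), names(comp$s_sub)))
  pos_keys <- unique(c(names(comp$e_ster), names(comp$s_ster)))
  if (length(intersect(pair_keys, pos_keys))) {
    stop("position-pair keys must not overlap single-position keys",
         call. = FALSE)
  }
  structure(c(comp, list(source = source)), class = "increment_table")
}

#' @export
print.increment_table <- function(x, ...) {
  cat("<increment table>",
      if (!is.null(x$source)) paste0(" (source: ", x$source, ")"), "\n",
      sep = "")
  show <- function(label, v) {
    if (!length(v)) return(invisible())
    cat("  ", label, ":\n", sep = "")
    for (k in names(v)) cat(sprintf("    %-10s %8.3f kcal/mol\n", k, v[[k]]))
  }
  show("IE-SUB (activation energy, pairs 1/3 and 2/4)", x$e_sub)
  show("IE-STER (activation energy, positions 1 and 4)", x$e_ster)
  show("IS-SUB (second minimum)", x$s_sub)
  show("IS-STER (second minimum)", x$s_ster)
  show("IE-DIST (distal ring)", x$e_dist)
  show("IS-DIST (distal ring)", x$s_dist)
  invisible(x)
}

#' Packaged empirical increment table
#'
#' The published empirical increments for the activation energy and the
#' second minimum of the proton transfer, derived from the para and meta
#' compound groups.  Shipped as plain-text JSON under `extdata` and used
#' as the default ground truth of the synthetic-data generator.
#'
#' @return An `increment_table` with `source = "literature"`.
#' @export
empirical_increments <- function() {
  read_increments(system.file("extdata", "empirical_increments.json", package = "hbridge",
                              mustWork = TRUE))
}

#' Read / write an increment table
#'
#' JSON files store one object per component (`e_sub`, `s_sub`,
#' `e_ster`, `s_ster`, `e_dist`, `s_dist`) mapping keys to kcal/mol
#' values; CSV files store `component,key,value` rows.  The format is
#' chosen from the file extension.
#'
#' @param path file to read or write (`.json` or `.csv`).
#' @return `read_increments()` returns an `increment_table`;
#'   `write_increments()` returns `path` invisibly.
#' @export
read_increments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  comps <- c("e_sub", "s_sub", "e_ster", "s_ster", "e_dist", "s_dist")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("component", "key", "value") %in% names(df)))
    args <- lapply(comps, function(cc) {
      rows <- df[df$component == cc, , drop = FALSE]
      stats::setNames(as.numeric(rows$value), rows$key)
    })
    names(args) <- comps
    return(do.call(increment_table, c(args, list(source = "file"))))
  }
  raw <- jsonlite::fromJSON(path)
  args <- lapply(comps, function(cc) {
    v <- raw[[cc]]
    if (is.null(v) || !length(v)) return(numeric(0))
    stats::setNames(as.numeric(unlist(v)), names(v))
  })
  names(args) <- comps
  do.call(increment_table, c(args, list(source = raw$source)))
}

#' @rdname read_increments
#' @param table an `increment_table`.
#' @export
write_increments <- function(table, path) {
  stopifnot(inherits(table, "increment_table"))
  comps <- c("e_sub", "s_sub", "e_ster", "s_ster", "e_dist", "s_dist")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(comps, function(cc) {
      v <- table[[cc]]
      if (!length(v)) return(NULL)
      data.frame(component = cc, key = names(v), value = unname(v),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- lapply(table[comps], as.list)
    out$source <- table$source
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Base (parent-compound) bridge parameters
#'
#' `EBC`/`SBC`: activation energy and second minimum of an unsubstituted
#' parent compound, the intercepts of the additive model.  One row per
#' group.
#'
#' @param group character vector of parent groups.
#' @param e_base,s_base activation energy and second minimum, kcal/mol;
#'   recycled against `group`.  Must satisfy `e_base >= s_base >= 0`.
#' @return A data frame with columns `group`, `e_base`, `s_base`.
#' @export
base_parameters <- function(group, e_base, s_base) {
  group <- match.arg(as.character(group), GROUPS, several.ok = TRUE)
  out <- data.frame(group = group, e_base = as.numeric(e_base),
                    s_base = as.numeric(s_base), stringsAsFactors = FALSE)
  if (any(out$e_base < out$s_base) || any(out$s_base < 0)) {
    stop("base parameters must satisfy e_base >= s_base >= 0",
         call. = FALSE)
  }
  out
}

# Bases from the unsubstituted record of each group.
derive_bases <- function(dataset, groups) {
  unsub <- dataset[dataset$proximal == "None,None" &
                     dataset$distal == "None,None", , drop = FALSE]
  rows <- lapply(groups, function(g) {
    sel <- unsub[unsub$group == g, , drop = FALSE]
    if (!nrow(sel)) {
      stop("no unsubstituted record for group '", g,
           "'; supply base parameters explicitly", call. = FALSE)
    }
    data.frame(group = g, e_base = mean(sel$ea), s_base = mean(sel$sm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

base_row <- function(bases, group) {
  row <- bases[bases$group == group, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("no base parameters for group '", group, "'", call. = FALSE)
  }
  row
}

# Mean EA/SM of proximal-monosubstituted records (distal unsubstituted).
proximal_mono_value <- function(dataset, group, label) {
  sel <- dataset[dataset$group == group & dataset$proximal == label &
                   dataset$distal == "None,None" &
                   dataset$has_pt_minimum, , drop = FALSE]
  if (!nrow(sel)) return(c(ea = NA_real_, sm = NA_real_))
  c(ea = mean(sel$ea), sm = mean(sel$sm))
}

#' Fit the composite-substituent-effect increments
#'
#' Recovers the substituent (`IE-SUB`/`IS-SUB`) and steric
#' (`IE-STER`/`IS-STER`) increments from proximal mono-substitution
#' records (distal ring unsubstituted).  Writing
#' `delta_g(p) = EA(substituent at proximal position p, group g) - EBC(g)`,
#' the classical substituent effect is taken as identical within the
#' position pairs 1/3 and 2/4, so:
#' * `IE-SUB(S, 1/3)` = mean over groups of `delta_g(3)`;
#' * `IE-SUB(S, 2/4)` = mean over groups of `delta_g(2)`;
#' * `IE-STER(S, 1)` = mean over groups of `delta_g(1) - delta_g(3)`;
#' * `IE-STER(S, 4)` = mean over groups of `delta_g(4) - delta_g(2)`;
#'
#' and identically for the second minimum with `SM` and `SBC`.  Groups
#' contribute with equal weight; the default groups are `para` and
#' `meta`, whose bridges are effectively uncoupled -- including `ortho`,
#' where the two bridges correlate, draws a warning.
#'
#' @param dataset a `bridge_dataset`.
#' @param bases base parameters (from [base_parameters()] or
#'   [derive_bases()]); when `NULL` they are taken from each group's
#'   unsubstituted record.
#' @param groups groups averaged over (default `c("para", "meta")`).
#' @param method `"average"` (the pairwise rules above, default) or
#'   `"ls"` (equivalent constrained least-squares fit over all four
#'   positions per substituent; identical on noiseless additive data).
#' @return A fitted `increment_table` (`source = "fitted"`).  Substituents
#'   lacking the position-3 or position-2 records needed to anchor their
#'   pair increments are reported in `attr(, "unfit")` and left out.
#' @export
fit_increments <- function(dataset, bases = NULL,
                           groups = c("para", "meta"),
                           method = c("average", "ls")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "bridge_dataset"))
  groups <- match.arg(groups, GROUPS, several.ok = TRUE)
  if ("ortho" %in% groups) {
    warning("including the ortho group: its two bridges are strongly ",
            "coupled, which the additive model does not describe",
            call. = FALSE)
  }
  if (is.null(bases)) bases <- derive_bases(dataset, groups)

  # delta[group, position] per substituent, for EA and SM
  deltas <- function(substituent) {
    ea <- sm <- matrix(NA_real_, length(groups), 4,
                       dimnames = list(groups, NULL))
    for (g in groups) {
      b <- base_row(bases, g)
      for (p in POSITIONS) {
        v <- proximal_mono_value(dataset, g, paste0(substituent, ",", p))
        ea[g, p] <- v[["ea"]] - b$e_base
        sm[g, p] <- v[["sm"]] - b$s_base
      }
    }
    list(ea = ea, sm = sm)
  }

  e_sub <- s_sub <- e_ster <- s_ster <- numeric(0)
  unfit <- character(0)
  for (S in SUBSTITUENTS) {
    d <- deltas(S)
    if (all(is.na(d$ea))) next  # substituent absent from the dataset
    if (all(is.na(d$ea[, 3])) || all(is.na(d$ea[, 2]))) {
      unfit <- c(unfit, S)
      next
    }
    fitted <- switch(method,
                     average = fit_substituent_average(d),
                     ls = fit_substituent_ls(d))
    e_sub <- c(e_sub, stats::setNames(fitted$e_sub,
                                      paste0(S, ":", names(fitted$e_sub))))
    s_sub <- c(s_sub, stats::setNames(fitted$s_sub,
                                      paste0(S, ":", names(fitted$s_sub))))
    e_ster <- c(e_ster, stats::setNames(fitted$e_ster,
                                        paste0(S, ":", names(fitted$e_ster))))
    s_ster <- c(s_ster, stats::setNames(fitted$s_ster,
                                        paste0(S, ":", names(fitted$s_ster))))
  }
  if (length(unfit)) {
    message("increments not fitted (missing position-3 or position-2 ",
            "records): ", paste(unfit, collapse = ", "))
  }
  out <- increment_table(e_sub = e_sub, s_sub = s_sub, e_ster = e_ster,
                         s_ster = s_ster, source = "fitted")
  attr(out, "unfit") <- unfit
  attr(out, "groups") <- groups
  out
}

fit_substituent_average <- function(d) {
  one <- function(m) {
    sub <- c("13" = mean(m[, 3], na.rm = TRUE),
             "24" = mean(m[, 2], na.rm = TRUE))
    ster <- c("1" = mean(m[, 1] - m[, 3], na.rm = TRUE),
              "4" = mean(m[, 4] - m[, 2], na.rm = TRUE))
    list(sub = sub[!is.na(sub)], ster = ster[!is.nan(ster) & !is.na(ster)])
  }
  ea <- one(d$ea); sm <- one(d$sm)
  list(e_sub = ea$sub, s_sub = sm$sub, e_ster = ea$ster, s_ster = sm$ster)
}

fit_substituent_ls <- function(d) {
  one <- function(m) {
    obs <- as.vector(m)                       # groups x positions
    pos <- rep(POSITIONS, each = nrow(m))
    keep <- !is.na(obs)
    X <- cbind("13" = as.numeric(pos %in% c(1, 3)),
               "24" = as.numeric(pos %in% c(2, 4)),
               "1" = as.numeric(pos == 1),
               "4" = as.numeric(pos == 4))[keep, , drop = FALSE]
    fit <- stats::lm.fit(X, obs[keep])
    cf <- fit$coefficients
    list(sub = cf[c("13", "24")][!is.na(cf[c("13", "24")])],
         ster = cf[c("1", "4")][!is.na(cf[c("1", "4")])])
  }
  ea <- one(d$ea); sm <- one(d$sm)
  list(e_sub = ea$sub, s_sub = sm$sub, e_ster = ea$ster, s_ster = sm$ster)
}

#' Estimate distal-ring increments
#'
#' The distal contribution of a pattern `d` is the shift it induces in
#' an otherwise identical view: the mean, over matched record pairs
#' differing only in the distal pattern (same group, same proximal
#' pattern, reference distal unsubstituted), of
#' `EA(proximal, distal d) - EA(proximal, distal none)`; analogously for
#' the second minimum.  Distal shifts are small -- below about
#' 0.5 kcal/mol in magnitude for these compounds.
#'
#' @inheritParams fit_increments
#' @param table increment table to extend.
#' @return The `increment_table` with `e_dist`/`s_dist` filled in for
#'   every distal pattern that has at least one matched pair.
#' @export
estimate_distal_increments <- function(dataset, table,
                                       groups = c("para", "meta")) {
  stopifnot(inherits(dataset, "bridge_dataset"),
            inherits(table, "increment_table"))
  groups <- match.arg(groups, GROUPS, several.ok = TRUE)
  rows <- dataset[dataset$group %in% groups & dataset$has_pt_minimum, ,
                  drop = FALSE]
  subst <- rows[rows$distal != "None,None", , drop = FALSE]
  e_dist <- s_dist <- numeric(0)
  for (d in unique(subst$distal)) {
    sel <- subst[subst$distal == d, , drop = FALSE]
    de <- ds <- numeric(0)
    for (i in seq_len(nrow(sel))) {
      ref <- rows[rows$group == sel$group[i] &
                    rows$proximal == sel$proximal[i] &
                    rows$distal == "None,None", , drop = FALSE]
      if (!nrow(ref)) next
      de <- c(de, sel$ea[i] - mean(ref$ea))
      ds <- c(ds, sel$sm[i] - mean(ref$sm))
    }
    if (length(de)) {
      e_dist[d] <- mean(de)
      s_dist[d] <- mean(ds)
    }
  }
  increment_table(e_sub = table$e_sub, s_sub = table$s_sub,
                  e_ster = table$e_ster, s_ster = table$s_ster,
                  e_dist = e_dist, s_dist = s_dist,
                  source = table$source)
}

#' Predict bridge parameters for a substitution view
#'
#' Evaluates the additive model for one (proximal, distal) view:
#' `EA = EBC + IE-SUB + IE-STER + IE-DIST` and
#' `SM = SBC + IS-SUB + IS-STER + IS-DIST`, where the steric term
#' applies only when the proximal position is 1 or 4 and the distal
#' terms only when the table carries distal increments.  A distal
#' pattern missing from a table that does carry distal increments falls
#' back to the proximal-only model with a warning.
#'
#' @param table an `increment_table`.
#' @param base a single-row data frame (or list) with `e_base`,
#'   `s_base`, e.g. one row of [base_parameters()].
#' @param proximal,distal substitution patterns (objects or labels);
#'   `distal` defaults to unsubstituted.
#' @return An object of class `bridge_prediction`: `ea`, `sm`
#'   (exact sums of the itemised contributions) and `components`, a data
#'   frame with one row per term (`base`, `sub`, `ster`, `dist`).
#' @examples
#' tab <- empirical_increments()
#' predict_bridge(tab, list(e_base = 10, s_base = 8), "Br,1")
#' @export
predict_bridge <- function(table, base, proximal, distal = "None,None") {
  stopifnot(inherits(table, "increment_table"))
  prox <- as_pattern(proximal)
  dist <- as_pattern(distal)
  e_base <- as.numeric(base$e_base)
  s_base <- as.numeric(base$s_base)
  if (!length(e_base) || !length(s_base) || is.na(e_base) || is.na(s_base)) {
    stop("base must supply scalar e_base and s_base", call. = FALSE)
  }

  e_sub <- s_sub <- e_ster <- s_ster <- 0
  if (!is.na(prox$substituent)) {
    key <- sub_pair_key(prox$substituent, prox$position)
    if (!key %in% names(table$e_sub)) {
      stop("increment table has no substituent entry '", key, "'",
           call. = FALSE)
    }
    e_sub <- table$e_sub[[key]]
    s_sub <- if (key %in% names(table$s_sub)) table$s_sub[[key]] else NA_real_
    if (prox$position %in% c(1L, 4L)) {
      skey <- ster_key(prox$substituent, prox$position)
      if (!skey %in% names(table$e_ster)) {
        stop("increment table has no steric entry '", skey, "'",
             call. = FALSE)
      }
      e_ster <- table$e_ster[[skey]]
      s_ster <- if (skey %in% names(table$s_ster)) table$s_ster[[skey]]
                else NA_real_
    }
  }

  e_dist <- s_dist <- 0
  if (!is.na(dist$substituent) && length(table$e_dist)) {
    dkey <- format_pattern_label(dist)
    if (dkey %in% names(table$e_dist)) {
      e_dist <- table$e_dist[[dkey]]
      s_dist <- if (dkey %in% names(table$s_dist)) table$s_dist[[dkey]] else 0
    } else {
      warning("distal pattern '", dkey, "' absent from the increment ",
              "table; falling back to the proximal-only model",
              call. = FALSE)
    }
  }

  components <- data.frame(
    term = c("base", "sub", "ster", "dist"),
    ea = c(e_base, e_sub, e_ster, e_dist),
    sm = c(s_base, s_sub, s_ster, s_dist),
    stringsAsFactors = FALSE)
  structure(list(ea = sum(components$ea), sm = sum(components$sm),
                 components = components,
                 proximal = format_pattern_label(prox),
                 distal = format_pattern_label(dist)),
            class = "bridge_prediction")
}

#' @export
print.bridge_prediction <- function(x, ...) {
  cat(sprintf("<prediction> proximal %s, distal %s: EA = %.3f, SM = %.3f kcal/mol\n",
              x$proximal, x$distal, x$ea, x$sm))
  invisible(x)
}

#' Relative approximation error of a prediction
#'
#' `100 * |predicted - actual| / |actual|`, separately for the
#' activation energy and the second minimum.  An actual value of 0 makes
#' the relative error undefined; it is returned as `NA` with a flag.
#'
#' @param actual a `bridge_parameters` object, or anything with fields
#'   `ea`/`activation_energy` and `sm`/`second_minimum`.
#' @param predicted a `bridge_prediction`, or anything with `ea`/`sm`.
#' @return An object of class `approx_error`: `ea_percent`,
#'   `sm_percent`, absolute deviations `ea_abs`/`sm_abs` (kcal/mol) and
#'   `flags`.
#' @export
approximation_error <- function(actual, predicted) {
  get2 <- function(x, a, b) {
    v <- if (!is.null(x[[a]])) x[[a]] else x[[b]]
    as.numeric(v)
  }
  a_ea <- get2(actual, "activation_energy", "ea")
  a_sm <- get2(actual, "second_minimum", "sm")
  if (isFALSE(actual[["has_pt_minimum"]])) {
    stop("actual parameters have no proton-transfer minimum", call. = FALSE)
  }
  p_ea <- get2(predicted, "ea", "activation_energy")
  p_sm <- get2(predicted, "sm", "second_minimum")
  flags <- character(0)
  rel <- function(p, a, what) {
    if (a == 0) {
      flags <<- c(flags, paste0("zero_actual_", what))
      return(NA_real_)
    }
    100 * abs(p - a) / abs(a)
  }
  out <- structure(list(ea_percent = rel(p_ea, a_ea, "ea"),
                        sm_percent = rel(p_sm, a_sm, "sm"),
                        ea_abs = abs(p_ea - a_ea),
                        sm_abs = abs(p_sm - a_sm),
                        flags = flags),
                   class = "approx_error")
  if (length(flags)) {
    warning("relative error undefined for zero actual value (",
            paste(flags, collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Dataset-level approximation-error report
#'
#' Predicts every record of a dataset from an increment table and the
#' per-group base parameters, and reports per-record and summary
#' (max, mean) relative errors for EA and SM.
#'
#' @inheritParams fit_increments
#' @param table an `increment_table`.
#' @return An object of class `approx_report`: `records` (data frame
#'   with per-record predictions, percent and absolute errors) and
#'   `summary` (named list with `max_ea_percent`, `mean_ea_percent`,
#'   `max_sm_percent`, `mean_sm_percent`, and the absolute analogues).
#' @export
approximation_report <- function(dataset, table, bases = NULL,
                                 groups = NULL) {
  stopifnot(inherits(dataset, "bridge_dataset"))
  if (is.null(groups)) groups <- sort(unique(dataset$group))
  rows <- dataset[dataset$group %in% groups & dataset$has_pt_minimum, ,
                  drop = FALSE]
  if (is.null(bases)) bases <- derive_bases(rows, groups)
  n <- nrow(rows)
  ea_pred <- sm_pred <- numeric(n)
  for (i in seq_len(n)) {
    p <- predict_bridge(table, base_row(bases, rows$group[i]),
                        rows$proximal[i], rows$distal[i])
    ea_pred[i] <- p$ea
    sm_pred[i] <- p$sm
  }
  rec <- data.frame(group = rows$group, proximal = rows$proximal,
                    distal = rows$distal,
                    ea = rows$ea, ea_pred = ea_pred,
                    sm = rows$sm, sm_pred = sm_pred,
                    stringsAsFactors = FALSE)
  rec$ea_abs <- abs(rec$ea_pred - rec$ea)
  rec$sm_abs <- abs(rec$sm_pred - rec$sm)
  rec$ea_percent <- ifelse(rec$ea == 0, NA_real_, 100 * rec$ea_abs / abs(rec$ea))
  rec$sm_percent <- ifelse(rec$sm == 0, NA_real_, 100 * rec$sm_abs / abs(rec$sm))
  summ <- list(max_ea_percent = max(rec$ea_percent, na.rm = TRUE),
               mean_ea_percent = mean(rec$ea_percent, na.rm = TRUE),
               max_sm_percent = max(rec$sm_percent, na.rm = TRUE),
               mean_sm_percent = mean(rec$sm_percent, na.rm = TRUE),
               max_ea_abs = max(rec$ea_abs), mean_ea_abs = mean(rec$ea_abs),
               max_sm_abs = max(rec$sm_abs), mean_sm_abs = mean(rec$sm_abs))
  structure(list(records = rec, summary = summ), class = "approx_report")
}

#' @export
print.approx_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<approximation report> %d records\n", nrow(x$records)))
  cat(sprintf("  EA: max %.3f%%, mean %.3f%% (max %.4f kcal/mol)\n",
              s$max_ea_percent, s$mean_ea_percent, s$max_ea_abs))
  cat(sprintf("  SM: max %.3f%%, mean %.3f%% (max %.4f kcal/mol)\n",
              s$max_sm_percent, s$mean_sm_percent, s$max_sm_abs))
  invisible(x)
}
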