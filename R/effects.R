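SKELETON_ATOMS <- c("C1", "C2", "C3", "C4", "C5", "C6", "CB", "O", "N", "H")

#' Proximal-by-distal matrix of one bridge parameter
#'
#' Arranges one scalar parameter of a dataset (activation energy `"ea"`,
#' second minimum `"sm"`, their difference `"diff"`, or any auxiliary
#' column) on the canonical substitution grid of one group: rows are
#' proximal patterns, columns distal patterns, both ordered
#' unsubstituted first, then `Br`, `NH2`, `NO2` over positions 1-4.
#' Combinations absent from the dataset are `NA` cells; cells matched by
#' several records (the two symmetric bridge views of one compound)
#' average them.
#'
#' @param dataset a `bridge_dataset`.
#' @param group single group to tabulate.
#' @param parameter column name of the scalar to tabulate.
#' @return A numeric matrix of class `bridge_matrix` with attributes
#'   `parameter` and `group`.
#' @export
build_matrix <- function(dataset, group, parameter = "ea") {
  stopifnot(inherits(dataset, "bridge_dataset"))
  group <- match.arg(as.character(group), GROUPS)
  if (!parameter %in% names(dataset)) {
    stop("unknown parameter '", parameter, "'; dataset columns: ",
         paste(setdiff(names(dataset), c("group", "ringA", "ringB",
                                         "bridge", "proximal", "distal")),
               collapse = ", "), call. = FALSE)
  }
  rows <- dataset[dataset$group == group, , drop = FALSE]
  labs <- all_patterns()
  prox <- intersect(labs, unique(rows$proximal))
  dist <- intersect(labs, unique(rows$distal))
  m <- matrix(NA_real_, length(prox), length(dist),
              dimnames = list(proximal = prox, distal = dist))
  vals <- rows[[parameter]]
  if ("has_pt_minimum" %in% names(rows) && parameter %in% c("ea", "sm", "diff")) {
    vals[!rows$has_pt_minimum] <- NA_real_
  }
  for (i in seq_len(nrow(rows))) {
    r <- rows$proximal[i]; c <- rows$distal[i]
    v <- vals[i]
    if (is.na(v)) next
    m[r, c] <- if (is.na(m[r, c])) v else mean(c(m[r, c], v))
  }
  structure(m, parameter = parameter, group = group,
            class = c("bridge_matrix", class(m)))
}

#' @export
print.bridge_matrix <- function(x, ...) {
  cat("<bridge matrix> ", attr(x, "group"), " / ", attr(x, "parameter"),
      ": ", nrow(x), " proximal x ", ncol(x), " distal patterns\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Proximal-versus-distal spread statistics
#'
#' Quantifies how strongly the tabulated parameter varies with the
#' proximal as opposed to the distal substitution.  The proximal spread
#' is the sample standard deviation down each column (variation across
#' proximal patterns at fixed distal pattern), summarised as mean and SD
#' over columns; the distal spread is the row-wise analogue.  Columns or
#' rows with fewer than two present values are excluded with a warning.
#'
#' @param matrix a `bridge_matrix` (or plain numeric matrix) with at
#'   least 2 rows and 2 columns.
#' @return An object of class `effect_spread` with fields
#'   `proximal_sd_mean`, `proximal_sd_sd`, `distal_sd_mean`,
#'   `distal_sd_sd` (kcal/mol) plus the per-column/-row SDs in
#'   `proximal_sds` / `distal_sds`.
#' @export
effect_spread <- function(matrix) {
  m <- unclass(matrix)
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least a 2 x 2 matrix to compare spreads", call. = FALSE)
  }
  slice_sds <- function(slices, what) {
    n_ok <- vapply(slices, function(v) sum(!is.na(v)), integer(1))
    if (any(n_ok < 2)) {
      warning(sum(n_ok < 2), " ", what,
              "(s) with fewer than 2 values excluded", call. = FALSE)
    }
    vapply(slices[n_ok >= 2], function(v) stats::sd(v, na.rm = TRUE),
           numeric(1))
  }
  col_sds <- slice_sds(asplit(m, 2), "column")
  row_sds <- slice_sds(asplit(m, 1), "row")
  if (!length(col_sds) || !length(row_sds)) {
    stop("not enough data to compute spread statistics", call. = FALSE)
  }
  structure(list(proximal_sd_mean = mean(col_sds),
                 proximal_sd_sd = if (length(col_sds) > 1) stats::sd(col_sds) else 0,
                 distal_sd_mean = mean(row_sds),
                 distal_sd_sd = if (length(row_sds) > 1) stats::sd(row_sds) else 0,
                 proximal_sds = col_sds,
                 distal_sds = row_sds),
            class = "effect_spread")
}

#' @export
print.effect_spread <- function(x, ...) {
  cat(sprintf("<effect spread> proximal %.2f +/- %.2f, distal %.2f +/- %.2f kcal/mol\n",
              x$proximal_sd_mean, x$proximal_sd_sd,
              x$distal_sd_mean, x$distal_sd_sd))
  invisible(x)
}

as_charge_set <- function(x) {
  if (is.data.frame(x)) {
    lab_col <- intersect(c("atom_label", "atom", "label"), names(x))[1]
    val_col <- intersect(c("charge", "value"), names(x))[1]
    if (is.na(lab_col) || is.na(val_col)) {
      stop("charge table needs an atom-label and a charge column",
           call. = FALSE)
    }
    x <- stats::setNames(as.numeric(x[[val_col]]), as.character(x[[lab_col]]))
  }
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("charges must be uniquely labelled by atom", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("charges must be finite", call. = FALSE)
  x
}

#' Charge differences against an unsubstituted reference
#'
#' Substituent effects on the electronic structure are best seen not in
#' the partial charges themselves but in their shift relative to the
#' unsubstituted counterpart.  Skeleton atoms (`C1`-`C6`, `CB`, `O`,
#' `N`, `H`) are differenced against the reference; atoms introduced by
#' the substituent itself have no counterpart and are reported
#' separately.
#'
#' @param charges named numeric vector (or `atom_label,charge` data
#'   frame) of partial charges, e, for a substituted structure.
#' @param base same for the unsubstituted reference; must contain every
#'   skeleton atom present in `charges`.
#' @return A list with `delta` (named differences, substituted minus
#'   base) and `substituent_only` (charges of substituent-introduced
#'   atoms).
#' @export
charge_delta <- function(charges, base) {
  charges <- as_charge_set(charges)
  base <- as_charge_set(base)
  skeleton <- intersect(names(charges), union(SKELETON_ATOMS, names(base)))
  missing <- setdiff(intersect(names(charges), SKELETON_ATOMS), names(base))
  if (length(missing)) {
    stop("reference charge set is missing skeleton atom(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(skeleton, names(base))
  list(delta = charges[shared] - base[shared],
       substituent_only = charges[setdiff(names(charges), names(base))])
}

#' Correlation of the distal-ring charge sum with the activation energy
#'
#' In the para and meta groups, where the two bridges are effectively
#' uncoupled, the activation energy tracks the summed partial charge on
#' the distal ring almost exclusively.  This computes the Pearson
#' correlation and least-squares line between a distal charge-sum
#' auxiliary column and EA for one group.
#'
#' @param dataset a `bridge_dataset` carrying the charge-sum column.
#' @param group group to analyse.
#' @param charge_column name of the auxiliary column (default
#'   `"distal_charge_sum"`).
#' @return An object of class `charge_correlation`: `r`, `n`, `slope`,
#'   `intercept`.
#' @export
distal_charge_correlation <- function(dataset, group,
                                      charge_column = "distal_charge_sum") {
  stopifnot(inherits(dataset, "bridge_dataset"))
  if (!charge_column %in% names(dataset)) {
    stop("dataset has no column '", charge_column, "'", call. = FALSE)
  }
  rows <- dataset[dataset$group == group & dataset$has_pt_minimum, ,
                  drop = FALSE]
  q <- rows[[charge_column]]
  ea <- rows$ea
  keep <- !is.na(q) & !is.na(ea)
  q <- q[keep]; ea <- ea[keep]
  if (length(q) < 3) {
    stop("need at least 3 records with charge sums and EA; got ",
         length(q), call. = FALSE)
  }
  if (stats::sd(q) == 0 || stats::sd(ea) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(q) == 0) "charge sums" else "activation energies",
         call. = FALSE)
  }
  fit <- stats::lm(ea ~ q)
  structure(list(r = stats::cor(q, ea), n = length(q),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 group = group),
            class = "charge_correlation")
}

#' @export
print.charge_correlation <- function(x, ...) {
  cat(sprintf("<charge correlation> %s: r = %.3f (n = %d), EA = %.3f q + %.3f\n",
              x$group, x$r, x$n, x$slope, x$intercept))
  invisible(x)
}

#' Heatmap of a bridge matrix
#'
#' Renders one `bridge_matrix` in the layout used throughout this kind
#' of analysis: proximal patterns as rows, distal patterns as columns,
#' a continuous fill for the parameter.  Use [patchwork-style
#' composition][ggplot2::ggplot] of three calls for the usual
#' EA / SM / difference triptych.
#'
#' @param matrix a `bridge_matrix`.
#' @return A `ggplot` object.
#' @export
plot_bridge_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "bridge_matrix"))
  df <- expand.grid(proximal = rownames(matrix), distal = colnames(matrix),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(unclass(matrix))
  df$proximal <- factor(df$proximal, levels = rev(rownames(matrix)))
  df$distal <- factor(df$distal, levels = colnames(matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distal, y = .data$proximal,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "distal pattern", y = "proximal pattern",
                  fill = paste0(attr(matrix, "parameter"), "\n[kcal/mol]"),
                  title = paste0(attr(matrix, "group"), " group: ",
                                 attr(matrix, "parameter"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
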