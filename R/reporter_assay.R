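#' Transfection-normalized reporter activity
#'
#' Firefly luciferase counts divided by the co-transfected Renilla
#' luciferase counts of the same well, removing well-to-well transfection
#' efficiency differences. The ratio is invariant to any common rescaling of
#' the two channels.
#'
#' @param firefly,renilla numeric vectors of luminescence counts
#'   (recycled against each other); all `renilla` must be positive.
#' @return numeric vector of normalized activities.
#' @export
normalized_activity <- function(firefly, renilla) {
  stopifnot(is.numeric(firefly), is.numeric(renilla),
            all(is.finite(firefly)), all(is.finite(renilla)))
  if (any(renilla <= 0)) stop("renilla counts must be positive")
  firefly / renilla
}

#' Fold activation of a reporter relative to a control
#'
#' Mean normalized activity of the treatment wells divided by the mean
#' normalized activity of the control wells (mean-of-ratios convention).
#' The standard error of the mean over treatment replicates, divided by the
#' control mean, is propagated alongside.
#'
#' @param treatment_wells,control_wells data.frames with `firefly` and
#'   `renilla` columns (one row per well), or numeric vectors of already
#'   normalized activities.
#' @return named numeric vector `c(fold, sem)`; `sem` is `NA` for a single
#'   treatment well.
#' @examples
#' trt <- data.frame(firefly = c(600, 800, 1000), renilla = 100)
#' ctl <- data.frame(firefly = 200, renilla = 100)
#' fold_activation(trt, ctl)  # fold 4
#' @export
fold_activation <- function(treatment_wells, control_wells) {
  norm <- function(w, nm) {
    if (is.data.frame(w)) {
      if (!all(c("firefly", "renilla") %in% names(w)))
        stop(nm, " must have firefly and renilla columns")
      normalized_activity(w$firefly, w$renilla)
    } else as.numeric(w)
  }
  t_act <- norm(treatment_wells, "treatment_wells")
  c_act <- norm(control_wells, "control_wells")
  if (!length(t_act) || !length(c_act))
    stop("both well groups must be non-empty")
  c_mean <- mean(c_act)
  if (c_mean == 0) stop("control mean activity is zero")
  sem <- if (length(t_act) > 1L)
    stats::sd(t_act) / sqrt(length(t_act)) / c_mean else NA_real_
  c(fold = mean(t_act) / c_mean, sem = sem)
}

#' Read a reporter-assay well table
#'
#' Tab-delimited table with columns `condition`, `firefly`, `renilla`.
#'
#' @param path path to the well table.
#' @return validated data.frame.
#' @export
read_wells <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  req <- c("condition", "firefly", "renilla")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("well table missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(is.numeric(df$firefly), is.numeric(df$renilla))
  if (any(df$renilla <= 0)) stop("renilla counts must be positive")
  df[req]
}

#' Fold activation of every condition against a control condition
#'
#' @param wells a well table (see [read_wells()]).
#' @param control the control condition label (default `"pCI"`).
#' @return data.frame with one row per non-control condition: `condition`,
#'   `fold`, `sem`.
#' @export
fold_activation_table <- function(wells, control = "pCI") {
  stopifnot(is.data.frame(wells),
            all(c("condition", "firefly", "renilla") %in% names(wells)))
  if (!control %in% wells$condition)
    stop("control condition '", control, "' not found")
  ctl <- wells[wells$condition == control, ]
  conds <- setdiff(unique(wells$condition), control)
  res <- lapply(conds, function(cd)
    fold_activation(wells[wells$condition == cd, ], ctl))
  data.frame(condition = conds,
             fold = vapply(res, `[[`, numeric(1L), "fold"),
             sem = vapply(res, `[[`, numeric(1L), "sem"),
             stringsAsFactors = FALSE)
}
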