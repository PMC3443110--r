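#' Keyword tally over annotation text
#'
#' Counts genes whose Gene Ontology Biological Process text contains any of
#' the keywords (case-insensitive plain substrings — the default tokens
#' "immun" and "inflamm" are deliberately prefixes, so "immune",
#' "autoimmunity" and "inflammatory" all match), and of those, how many are
#' Increased or Decreased in any of the supplied contrasts. A gene counts as
#' up if any contrast calls it Increased, so `n_up + n_down` may exceed
#' `n_matching` when directions differ between ages.
#'
#' @param annotations annotation data.frame with `gene_id` and `go_bp_text`
#'   columns (see [read_annotations()]).
#' @param effect_maps a single named effect vector or a list of them (see
#'   [effect_map()]); genes absent from a map are treated as Unchanged there.
#' @param keywords non-empty character vector of substrings.
#' @return object of class `keyword_tally`: list with `keywords`,
#'   `n_matching`, `n_up`, `n_down`, `pct_up` (100 * n_up / n_matching,
#'   one decimal), and `matching_ids`.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2"),
#'                   go_bp_text = c("immune response", "metabolism"))
#' keyword_tally(ann, list(c(g1 = "Increased", g2 = "Unchanged")))
#' @export
keyword_tally <- function(annotations, effect_maps,
                          keywords = c("immun", "inflamm")) {
  if (!length(keywords)) stop("keyword list must be non-empty")
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "go_bp_text") %in% names(annotations)))
    stop("annotations must have columns gene_id and go_bp_text")
  if (!is.list(effect_maps)) effect_maps <- list(effect_maps)
  txt <- tolower(as.character(annotations$go_bp_text))
  txt[is.na(txt)] <- ""
  hit <- rep(FALSE, length(txt))
  for (kw in tolower(keywords)) hit <- hit | grepl(kw, txt, fixed = TRUE)
  ids <- annotations$gene_id[hit]
  has_label <- function(lab) {
    any_lab <- rep(FALSE, length(ids))
    for (m in effect_maps) {
      lm <- as.character(m[ids])
      any_lab <- any_lab | (!is.na(lm) & lm == lab)
    }
    any_lab
  }
  n_up <- sum(has_label("Increased"))
  n_down <- sum(has_label("Decreased"))
  structure(list(keywords = keywords,
                 n_matching = length(ids), n_up = n_up, n_down = n_down,
                 pct_up = if (length(ids))
                   round(100 * n_up / length(ids), 1) else NA_real_,
                 matching_ids = ids),
            class = "keyword_tally")
}

#' @export
print.keyword_tally <- function(x, ...) {
  cat(sprintf("Keywords [%s]: %d matching genes; %d up (%.1f%%), %d down\n",
              paste(x$keywords, collapse = ", "),
              x$n_matching, x$n_up, x$pct_up, x$n_down))
  invisible(x)
}
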