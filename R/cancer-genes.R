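#' Apply a stability annotation to a candidate catalog
#'
#' Stability TSGs (genome-maintenance genes: DNA repair, cell-cycle
#' checkpoint, DNA-damage response) behave differently from classic growth
#' suppressors, so the catalog carries a boolean flag. The flag is taken
#' from a provided annotation table (e.g. a curated list plus GO-term
#' membership, supplied as input); genes absent from the annotation are
#' non-stability.
#'
#' @param catalog tibble with columns `gene`, `role`, `cancer_types` (and
#'   optionally an existing `stability` column, which is replaced).
#' @param stability_annotation character vector of stability gene ids, or a
#'   data frame whose first column holds them.
#' @return The catalog with its `stability` column set from the annotation.
#' @export
classify_stability <- function(catalog, stability_annotation) {
  if (is.data.frame(stability_annotation))
    stability_annotation <- stability_annotation[[1]]
  if (any(catalog$role == "oncogene" & catalog$gene %in% stability_annotation))
    warning("stability annotation lists oncogene(s); flag applies to TSGs only")
  catalog$stability <- catalog$role == "TSG" & catalog$gene %in% stability_annotation
  catalog
}

check_catalog <- function(catalog) {
  need <- c("gene", "role", "stability", "cancer_types")
  if (!all(need %in% names(catalog)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  both <- stats::aggregate(role ~ gene + cancer_types, catalog,
                           function(r) length(unique(r)))
  if (any(both$role > 1))
    stop("a gene may not be both oncogene and TSG for one cancer type")
  invisible(catalog)
}

direction_label <- function(direction, modality) {
  up <- c(expression = "up", methylation = "hyper", cna = "amp")
  down <- c(expression = "down", methylation = "hypo", cna = "del")
  ifelse(direction > 0, up[modality], down[modality])
}

#' Count candidate-gene direction events
#'
#' An event is one candidate gene showing one (consistency-retained) change
#' of one modality in its own cancer type. Each (gene, cancer, modality)
#' counts once regardless of input row order; the same gene altered in two
#' cancer types contributes two events.
#'
#' @param merged_calls tibble of merged consistent calls across cancers:
#'   columns `gene`, `direction`, `modality` plus `cancer_type`. Typically
#'   `merge_consistent()` output per cancer, row-bound with a `cancer_type`
#'   column added.
#' @param catalog a candidate catalog (see [check_catalog()] requirements);
#'   `cancer_types` is a semicolon-separated string per gene.
#' @return An event table: tibble (gene, cancer_type, modality, direction,
#'   role, stability) with `direction` in up/down, hyper/hypo, amp/del.
#' @export
count_direction_events <- function(merged_calls, catalog) {
  check_catalog(catalog)
  cat_long <- tidyr_unnest_types(catalog)
  ev <- dplyr::inner_join(merged_calls, cat_long,
                          by = c("gene", "cancer_type"))
  ev <- dplyr::distinct(ev, .data$gene, .data$cancer_type, .data$modality,
                        .keep_all = TRUE)
  tibble::tibble(
    gene = ev$gene, cancer_type = ev$cancer_type, modality = ev$modality,
    direction = unname(direction_label(ev$direction, ev$modality)),
    role = ev$role, stability = ev$stability
  )
}

# expand semicolon-separated cancer_types to one row per (gene, cancer)
tidyr_unnest_types <- function(catalog) {
  parts <- strsplit(catalog$cancer_types, ";", fixed = TRUE)
  n <- lengths(parts)
  tibble::tibble(
    gene = rep(catalog$gene, n),
    role = rep(catalog$role, n),
    stability = rep(catalog$stability, n),
    cancer_type = unlist(parts)
  )
}

#' Directional bias of a candidate-gene class
#'
#' For one gene class (e.g. non-stability TSGs) and one modality, the
#' fraction of events in the favored direction and the binomial probability
#' of at least that many favored events under a fair-coin null.
#'
#' @param events an event table from [count_direction_events()].
#' @param role `"oncogene"` or `"TSG"`.
#' @param favored_direction the direction the class is expected to show
#'   (`"up"`, `"down"`, `"hyper"`, `"hypo"`, `"amp"`, `"del"`).
#' @param modality which modality's events to test.
#' @param stability restrict to stability (`TRUE`) or non-stability
#'   (`FALSE`) genes; `NA` uses the whole class.
#' @return A list: `n_events`, `n_favored`, `frequency`, `p_value`,
#'   `genes_favored` (distinct genes behind the favored events). With zero
#'   events, `frequency` and `p_value` are `NA` and `empty` is `TRUE`.
#' @export
direction_bias_test <- function(events, role, favored_direction,
                                modality = "cna", stability = NA) {
  ev <- events[events$role == role & events$modality == modality, , drop = FALSE]
  if (!is.na(stability)) ev <- ev[ev$stability == stability, , drop = FALSE]
  n <- nrow(ev)
  if (n == 0)
    return(list(n_events = 0L, n_favored = 0L, frequency = NA_real_,
                p_value = NA_real_, genes_favored = character(0), empty = TRUE))
  fav <- ev$direction == favored_direction
  list(n_events = n, n_favored = sum(fav),
       frequency = sum(fav) / n,
       p_value = binomial_consistency_pvalue(n, sum(fav)),
       genes_favored = sort(unique(ev$gene[fav])), empty = FALSE)
}

#' Background direction frequency among all retained differential genes
#'
#' The expected frequency against which candidate-gene frequencies are
#' compared: the fraction of ALL retained (consistency-merged) differential
#' genes — candidates or not — changing in the given direction, per cancer
#' type and modality.
#'
#' @param merged_calls merged calls with `gene`, `direction`, `modality`,
#'   `cancer_type`.
#' @param direction `+1` (up/hyper/amp) or `-1`.
#' @param modality modality to restrict to.
#' @return Tibble (cancer_type, n_genes, n_direction, frequency).
#' @export
background_frequency <- function(merged_calls, direction, modality) {
  mc <- merged_calls[merged_calls$modality == modality, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(mc, .data$cancer_type),
    n_genes = dplyr::n(),
    n_direction = sum(.data$direction == !!direction),
    .groups = "drop"
  )
  out$frequency <- out$n_direction / out$n_genes
  out
}

#' Average a per-cancer event frequency
#'
#' The headline "average frequency" can be read two ways, so both are
#' returned: `pooled` sums favored and total events over cancers before
#' dividing (the default headline), `mean_per_cancer` averages the
#' per-cancer frequencies unweighted.
#'
#' @param events event table restricted to one class/modality (e.g. via the
#'   filtering done in [direction_bias_test()]).
#' @param favored_direction direction counted as favored.
#' @return List with `pooled`, `mean_per_cancer`, and the per-cancer table.
#' @export
average_frequency <- function(events, favored_direction) {
  per <- dplyr::summarise(
    dplyr::group_by(events, .data$cancer_type),
    n_events = dplyr::n(),
    n_favored = sum(.data$direction == favored_direction),
    .groups = "drop"
  )
  per$frequency <- per$n_favored / per$n_events
  list(pooled = sum(per$n_favored) / sum(per$n_events),
       mean_per_cancer = mean(per$frequency),
       per_cancer = per)
}
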