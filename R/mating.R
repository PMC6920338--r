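#' Validate a parent panel table
#'
#' A parent panel lists candidate parents with their varietal group and
#' whether the line is a maintainer. In the three-line system a maintainer's
#' nuclear genome matches its cytoplasmic male-sterile counterpart, so
#' maintainers serve as pseudo-female parents when enumerating in-silico
#' crosses.
#'
#' @param parent_id Character vector of unique line identifiers.
#' @param group Character vector of varietal group labels (one per parent),
#'   e.g. the rice subspecies groups in [rice_3k_groups].
#' @param is_maintainer Logical vector, one per parent.
#' @return A tibble with columns `parent_id`, `group`, `is_maintainer`.
#' @export
parent_panel <- function(parent_id, group, is_maintainer = FALSE) {
  panel <- tibble::tibble(parent_id = as.character(parent_id),
                          group = as.character(group),
                          is_maintainer = as.logical(is_maintainer))
  if (anyDuplicated(panel$parent_id)) {
    stop("parent ids must be unique.", call. = FALSE)
  }
  if (anyNA(panel$group) || anyNA(panel$is_maintainer)) {
    stop("every parent needs a group label and a maintainer flag.",
         call. = FALSE)
  }
  panel
}

#' Varietal groups of the 3000-accession rice panel
#'
#' The five subspecies groups used to describe the 3K rice germplasm:
#' Xian (indica), Geng (japonica), intermediate, aus/boro and
#' basmati/sadri.
#' @format Character vector of length 5.
#' @export
rice_3k_groups <- c("Xian", "Geng", "intermediate", "aus", "basmati")

as_panel <- function(panel) {
  panel <- as.data.frame(panel)
  need <- c("parent_id", "group", "is_maintainer")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns parent_id, group, is_maintainer.", call. = FALSE)
  }
  parent_panel(panel$parent_id, panel$group, panel$is_maintainer)
}

#' Enumerate permissible three-line crosses
#'
#' Crosses every maintainer (as pseudo-female) with every non-maintainer line
#' whose group pairing is allowed. Maintainer x maintainer pairs and
#' self-crosses are never produced; reciprocal duplicates cannot arise since
#' the female is always the maintainer.
#'
#' @param panel A parent panel (see [parent_panel()]).
#' @param allowed_pairs A data frame (or two-column matrix) of unordered group
#'   label pairs that may be crossed, female group first; e.g.
#'   `rice_3k_cross_rules()`. A pair is matched irrespective of order unless
#'   `ordered = TRUE`, in which case the first column must match the female
#'   (maintainer) group.
#' @param ordered Treat `allowed_pairs` rows as (female group, male group)
#'   ordered pairs. Default `FALSE`.
#'
#' @return A tibble with columns `hybrid_id`, `female`, `male`, `female_group`,
#'   `male_group`; zero rows (with a warning) when no pairing is allowed.
#' @export
enumerate_three_line_crosses <- function(panel, allowed_pairs,
                                         ordered = FALSE) {
  panel <- as_panel(panel)
  ap <- as.data.frame(allowed_pairs)
  if (ncol(ap) < 2 || nrow(ap) == 0) {
    stop("`allowed_pairs` needs >= 1 row and two group columns.",
         call. = FALSE)
  }
  females <- panel[panel$is_maintainer, ]
  males <- panel[!panel$is_maintainer, ]
  if (nrow(females) == 0) {
    stop("panel contains no maintainer line to use as female parent.",
         call. = FALSE)
  }
  key <- function(a, b) {
    if (ordered) paste(a, b, sep = "\r") else paste(pmin(a, b), pmax(a, b), sep = "\r")
  }
  allowed <- unique(key(as.character(ap[[1]]), as.character(ap[[2]])))
  crosses <- tidyr::expand_grid(female = females$parent_id,
                                male = males$parent_id)
  crosses <- dplyr::left_join(crosses,
    dplyr::select(panel, female = "parent_id", female_group = "group"),
    by = "female")
  crosses <- dplyr::left_join(crosses,
    dplyr::select(panel, male = "parent_id", male_group = "group"),
    by = "male")
  crosses <- crosses[key(crosses$female_group, crosses$male_group) %in% allowed &
                       crosses$female != crosses$male, ]
  if (nrow(crosses) == 0) {
    warning("no permissible crosses under the given rules.", call. = FALSE)
  }
  tibble::tibble(hybrid_id = hybrid_id(crosses$female, crosses$male),
                 female = crosses$female, male = crosses$male,
                 female_group = crosses$female_group,
                 male_group = crosses$male_group)
}

#' Cross-compatibility rules used for the 3K rice panel
#'
#' Within-subspecies pairings plus intermediate-type females on either
#' subspecies: Xian x Xian, Geng x Geng, intermediate x Xian and
#' intermediate x Geng.
#' @return A two-column tibble of allowed group pairs.
#' @export
rice_3k_cross_rules <- function() {
  tibble::tibble(
    female_group = c("Xian", "Geng", "intermediate", "intermediate"),
    male_group = c("Xian", "Geng", "Xian", "Geng")
  )
}

#' Half-diallel cross enumeration
#'
#' All unordered pairs of distinct parents (no selfs, no reciprocals),
#' optionally restricted to pairs from the same group (within-subspecies
#' crosses being the ones practical in hybrid rice breeding).
#'
#' @param panel A parent panel (see [parent_panel()]); the maintainer flag is
#'   ignored.
#' @param within_groups_only Drop pairs whose group labels differ. Default
#'   `FALSE`.
#' @return A tibble with columns `hybrid_id`, `parent1`, `parent2` (ids sorted
#'   within pair).
#' @export
half_diallel <- function(panel, within_groups_only = FALSE) {
  panel <- as_panel(panel)
  n <- nrow(panel)
  if (n < 2) stop("need at least two parents for a diallel.", call. = FALSE)
  idx <- utils::combn(n, 2)
  p1 <- panel$parent_id[idx[1, ]]
  p2 <- panel$parent_id[idx[2, ]]
  keep <- rep(TRUE, length(p1))
  if (within_groups_only) {
    keep <- panel$group[idx[1, ]] == panel$group[idx[2, ]]
  }
  tibble::tibble(hybrid_id = hybrid_id(p1[keep], p2[keep]),
                 parent1 = pmin(p1[keep], p2[keep]),
                 parent2 = pmax(p1[keep], p2[keep]))
}

#' Number of unordered pairs among n parents
#'
#' The size of the full single-cross space: n(n-1)/2.
#'
#' @param n Integer >= 2.
#' @return `n * (n - 1) / 2`.
#' @export
#' @examples
#' count_all_pairs(3000)  # 4498500
count_all_pairs <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2.", call. = FALSE)
  }
  n * (n - 1) / 2
}
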