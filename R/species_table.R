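#' Code diet categories from percent feeding times
#'
#' A species is frugivorous when plant reproductive parts (fruit, flowers,
#' seeds, buds, nectar) occupy strictly the largest share of feeding time
#' among the four categories, and folivorous when plant vegetative parts do.
#' Strict folivory additionally requires membership in a user-supplied list
#' of species with clear physiological adaptations for folivory. Ties are
#' coded as neither, with a warning.
#'
#' @param fauna,plant_repro,plant_veg,exudates Percent feeding time (each in
#'   \code{[0, 100]}; vectors are recycled to a common length).
#' @param strict_member Logical; is the species on the physiological
#'   folivory-adaptation list?
#' @return Data frame with logical columns \code{frugivorous},
#'   \code{folivorous}, \code{strict_folivorous}.
#' @export
classify_diet <- function(fauna, plant_repro, plant_veg, exudates,
                          strict_member = FALSE) {
  m <- cbind(fauna = fauna, plant_repro = plant_repro,
             plant_veg = plant_veg, exudates = exudates)
  if (any(m < 0, na.rm = TRUE)) stop("percent feeding times must be >= 0")
  if (any(rowSums(m, na.rm = TRUE) == 0)) stop("all-zero feeding percentages")
  strict_member <- rep_len(strict_member, nrow(m))
  top <- apply(m, 1, max)
  n_top <- rowSums(m == top)
  fru <- m[, "plant_repro"] == top & n_top == 1L
  fol <- m[, "plant_veg"] == top & n_top == 1L
  if (any(n_top > 1L & (m[, "plant_repro"] == top | m[, "plant_veg"] == top)))
    warning("tied feeding-time maxima: coded as neither frugivorous nor folivorous")
  data.frame(frugivorous = fru, folivorous = fol,
             strict_folivorous = fol & strict_member)
}

#' Bin average group size into the five ordered categories
#'
#' Values are rounded half-up to integers before binning, since the category
#' labels are integer bounds: 1-5, 6-10, 11-25, 26-50, >50.
#'
#' @param avg Positive average group size(s).
#' @return Ordered factor with levels \code{"1-5" < "6-10" < "11-25" <
#'   "26-50" < ">50"}.
#' @export
bin_group_size <- function(avg) {
  if (any(!is.finite(avg) | avg <= 0)) stop("average group size must be positive")
  r <- floor(avg + 0.5)  # round half up
  lv <- c("1-5", "6-10", "11-25", "26-50", ">50")
  idx <- findInterval(r, c(0, 6, 11, 26, 51))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Recode activity period to the diurnal/nocturnal dichotomy
#'
#' Cathemeral species are coded diurnal.
#'
#' @param x Character vector of activity labels.
#' @return Factor with levels \code{diurnal}, \code{nocturnal}.
#' @export
recode_activity <- function(x) {
  x <- tolower(as.character(x))
  x[x == "cathemeral"] <- "diurnal"
  bad <- setdiff(unique(x), c("diurnal", "nocturnal", NA))
  if (length(bad)) stop("unknown activity labels: ", paste(bad, collapse = ", "))
  factor(x, levels = c("diurnal", "nocturnal"))
}

.species_numeric_cols <- c("log_ecv", "log_ecv_var", "log_body_mass",
                           "log_body_mass_var", "group_size")
.species_pct_cols <- c("pct_fauna", "pct_plant_repro", "pct_plant_veg",
                       "pct_exudates")

#' Validate a species-level data table
#'
#' Checks the invariants the fitting machinery relies on: unique species,
#' non-negative observation variances, percentages in \code{[0, 100]}, and
#' (when a tree is supplied) that every species is a tip of the tree.
#'
#' @param df Data frame with at least a \code{species} column; recognized
#'   numeric columns are \code{log_ecv}, \code{log_ecv_var},
#'   \code{log_body_mass}, \code{log_body_mass_var}, \code{group_size} and
#'   the percent columns \code{pct_fauna}, \code{pct_plant_repro},
#'   \code{pct_plant_veg}, \code{pct_exudates}.
#' @param tree Optional tree for the tip-membership check.
#' @return \code{df} with class \code{species_table} prepended.
#' @export
species_table <- function(df, tree = NULL) {
  stopifnot(is.data.frame(df))
  if (!"species" %in% names(df)) stop("species column is required")
  if (anyDuplicated(df$species)) stop("duplicate species rows")
  for (cl in intersect(grep("_var$", names(df), value = TRUE), names(df)))
    if (any(df[[cl]] < 0, na.rm = TRUE)) stop("observation variances must be >= 0 (", cl, ")")
  for (cl in intersect(.species_pct_cols, names(df)))
    if (any(df[[cl]] < 0 | df[[cl]] > 100, na.rm = TRUE))
      stop("percent columns must lie in [0, 100] (", cl, ")")
  if (!is.null(tree)) {
    missing <- setdiff(df$species, tree$tip.label)
    if (length(missing))
      stop("species absent from the tree: ", paste(missing, collapse = ", "))
  }
  class(df) <- unique(c("species_table", class(df)))
  df
}

#' Read a species table from CSV
#'
#' One row per species, missing values as empty fields; columns as described
#' in \code{\link{species_table}}.
#'
#' @param path CSV path.
#' @param tree Optional tree for validation.
#' @return A \code{species_table}.
#' @export
read_species_table <- function(path, tree = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  species_table(df, tree = tree)
}
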