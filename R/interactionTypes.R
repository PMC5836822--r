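# Fine interaction-type labels and their aggregation into coarse groups.
# The coarse menu: activity and transport regulation; catalysis; coexpression;
# expression regulation; interaction. "expression" and "association" links
# participate only in the generalized "all types" count, via group "other",
# as do any labels not in the table.

.FINE_TO_COARSE <- c(
  "activity downregulation"    = "activity_and_transport_regulation",
  "activity regulation"        = "activity_and_transport_regulation",
  "activity upregulation"      = "activity_and_transport_regulation",
  "transport regulation"       = "activity_and_transport_regulation",
  "catalyze"                   = "catalysis",
  "cleavage"                   = "catalysis",
  "degradation downregulation" = "catalysis",
  "degradation regulation"     = "catalysis",
  "degradation upregulation"   = "catalysis",
  "coexpression"               = "coexpression",
  "expression upregulation"    = "expression_regulation",
  "expression downregulation"  = "expression_regulation",
  "expression regulation"      = "expression_regulation",
  "interaction"                = "interaction",
  "expression"                 = "other",
  "association"                = "other"
)

.COARSE_LEVELS <- c(
  "activity_and_transport_regulation", "catalysis", "coexpression",
  "expression_regulation", "interaction", "other"
)

.ALL_TYPES <- "all_types"

#' Coarse group of fine interaction-type labels
#'
#' Maps fine link labels (e.g. \code{"activity upregulation"},
#' \code{"catalyze"}) to one of six coarse groups. Labels absent from the
#' built-in table map to \code{"other"}, so they are counted only under the
#' generalized \code{"all_types"} filter.
#'
#' @param fine character vector of fine type labels.
#' @return Character vector of coarse group names, same length as \code{fine}.
#' @examples
#' coarseGroup(c("catalyze", "cleavage", "coexpression", "unheard-of"))
#' @export
coarseGroup <- function(fine) {
  out <- .FINE_TO_COARSE[fine]
  out[is.na(out)] <- "other"
  unname(out)
}

#' Coarse interaction-type groups
#'
#' @param withAllTypes also append the generalized \code{"all_types"} pseudo
#'   group accepted by the filtering functions.
#' @return Character vector of coarse group names.
#' @export
coarseGroupLevels <- function(withAllTypes = FALSE) {
  if (withAllTypes) c(.COARSE_LEVELS, .ALL_TYPES) else .COARSE_LEVELS
}

#' Built-in fine-to-coarse interaction-type table
#'
#' @return data.frame with columns \code{fine} and \code{coarse}.
#' @export
interactionTypeTable <- function() {
  data.frame(fine = names(.FINE_TO_COARSE),
             coarse = unname(.FINE_TO_COARSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

.checkCoarse <- function(coarse) {
  if (!is.character(coarse) || length(coarse) != 1L ||
      !(coarse %in% c(.COARSE_LEVELS, .ALL_TYPES)))
    stop("'coarse' must be one of: ",
         paste(c(.COARSE_LEVELS, .ALL_TYPES), collapse = ", "),
         call. = FALSE)
  coarse
}
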