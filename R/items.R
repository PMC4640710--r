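#' Item catalogue for the HCR-20v3 / SAPROF instrument pair
#'
#' Returns the catalogue of items the cohort generator and the analysis stages
#' operate on: the 10 historical (static), 5 clinical and 5 risk-management
#' items of the HCR-20v3, and the 17 protective items of the SAPROF. Each item
#' carries its scale, a human-readable name and a causal role:
#' \describe{
#'   \item{static}{historical items, rated once at baseline and held fixed.}
#'   \item{proximal}{items that act on violence directly in the concurrent
#'     window: violent ideation or intent, instability, stress or coping on the
#'     risk side, and self-control on the protective side.}
#'   \item{distal}{dynamic items whose association with violence runs entirely
#'     through the proximal items.}
#'   \item{protective}{SAPROF items other than self-control (distal on the
#'     protective side).}
#' }
#'
#' @return A data frame with columns \code{item_id}, \code{scale} (one of
#'   \code{"H"}, \code{"C"}, \code{"R"}, \code{"SAPROF"}), \code{name} and
#'   \code{role}.
#' @export
#' @examples
#' cat <- item_catalogue()
#' table(cat$scale, cat$role)
item_catalogue <- function() {
  h <- c("violence_history", "antisocial_behaviour", "relationships",
         "employment", "substance_use", "major_mental_disorder",
         "personality_disorder", "traumatic_experiences", "violent_attitudes",
         "treatment_response_h")
  cl <- c("lack_of_insight", "violent_ideation", "symptoms_mmd",
          "instability", "treatment_response_c")
  rm_ <- c("professional_services", "living_situation", "personal_support",
           "treatment_response_r", "stress_coping")
  sap <- c("intelligence", "secure_attachment", "empathy", "coping",
           "self_control", "work", "leisure_activities", "financial_management",
           "motivation_treatment", "attitudes_authority", "life_goals",
           "medication", "social_network", "intimate_relationship",
           "professional_care", "living_circumstances", "external_control")
  cat <- data.frame(
    item_id = c(paste0("H", seq_along(h)), paste0("C", seq_along(cl)),
                paste0("R", seq_along(rm_)), paste0("S", seq_along(sap))),
    scale = rep(c("H", "C", "R", "SAPROF"), c(length(h), length(cl),
                                              length(rm_), length(sap))),
    name = c(h, cl, rm_, sap),
    stringsAsFactors = FALSE
  )
  proximal <- c("violent_ideation", "instability", "stress_coping",
                "self_control")
  cat$role <- ifelse(cat$scale == "H", "static",
              ifelse(cat$name %in% proximal, "proximal",
              ifelse(cat$scale == "SAPROF", "protective", "distal")))
  cat
}

# item names by role/scale, used throughout the internals
items_of <- function(catalogue, scale = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(catalogue))
  if (!is.null(scale)) keep <- keep & catalogue$scale %in% scale
  if (!is.null(role)) keep <- keep & catalogue$role %in% role
  catalogue$name[keep]
}

# dynamic (wave-varying) items: everything except the historical scale
dynamic_items <- function(catalogue) items_of(catalogue)[catalogue$scale != "H"]

#' @rdname item_catalogue
#' @format NULL
#' @details \code{proximal_risk_items()}, \code{proximal_protective_item()},
#'   \code{distal_risk_items()} and \code{distal_protective_items()} are small
#'   accessors over the catalogue used when wiring simulations and attenuation
#'   analyses.
#' @export
proximal_risk_items <- function() c("violent_ideation", "instability", "stress_coping")

#' @rdname item_catalogue
#' @export
proximal_protective_item <- function() "self_control"

#' @rdname item_catalogue
#' @export
distal_risk_items <- function() {
  cat <- item_catalogue()
  items_of(cat, scale = c("C", "R"), role = "distal")
}

#' @rdname item_catalogue
#' @export
distal_protective_items <- function() {
  cat <- item_catalogue()
  items_of(cat, scale = "SAPROF", role = "protective")
}
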