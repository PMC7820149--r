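#' Trait categories and sensitivity scores
#'
#' Five macroinvertebrate trait categories index sensitivity to flood and
#' nutrient-enrichment disturbance, each scored so that higher values are
#' more sensitive. Body form: cylindrical 3, flattened 2, streamlined 1.
#' Locomotion: crawler 3, swimmer 2, burrower/sessile 1. Respiration:
#' gills/aerial 3, tegument 2, plastron 1. Dispersal: low 3, moderate 2,
#' high 1. Organic-enrichment sensitivity uses each taxon's
#' Macroinvertebrate Community Index (MCI) score verbatim (conventional
#' range 1-10).
#'
#' @format list of named numeric vectors, one per categorical trait.
#' @export
trait_score_map <- list(
  body_form = c(cylindrical = 3, flattened = 2, streamlined = 1),
  locomotion = c(crawler = 3, swimmer = 2, burrower_sessile = 1),
  respiration_mode = c(gills_aerial = 3, tegument = 2, plastron = 1),
  dispersal = c(low = 3, moderate = 2, high = 1)
)

#' Names of the five sensitivity-trait categories
#' @return character vector of trait names accepted by [score_traits].
#' @export
trait_categories <- function() c(names(trait_score_map), "mci")

#' Score taxa on one sensitivity trait
#'
#' @param traits data.frame with columns taxon, body_form, locomotion,
#'   respiration_mode, dispersal, mci_score.
#' @param category one of [trait_categories()].
#' @return named numeric vector of scores per taxon; `NA` marks taxa with
#'   a missing trait value (never defaulted).
#' @export
score_traits <- function(traits, category) {
  if (!category %in% trait_categories()) {
    stop("unknown trait category '", category, "'; allowed: ",
         paste(trait_categories(), collapse = ", "))
  }
  if (!"taxon" %in% names(traits)) stop("traits needs a 'taxon' column")
  if (category == "mci") {
    return(stats::setNames(as.numeric(traits$mci_score), traits$taxon))
  }
  map <- trait_score_map[[category]]
  vals <- as.character(traits[[category]])
  bad <- !is.na(vals) & !(vals %in% names(map))
  if (any(bad)) {
    stop("unknown ", category, " label(s): ",
         paste(unique(vals[bad]), collapse = ", "),
         "; allowed: ", paste(names(map), collapse = ", "))
  }
  stats::setNames(unname(map[vals]), traits$taxon)
}

#' Keystone Sensitivity Index
#'
#' The KSI of a web for one trait is the average-environ-centrality
#' (AEC) weighted mean of that trait's sensitivity scores over the
#' macroinvertebrate compartments:
#' `KSI = sum_m(score_m * AEC_m) / sum_m(AEC_m)`,
#' where `m` ranges over macroinvertebrates with a score. Taxa lacking a
#' score are excluded from both sums; `coverage` reports the fraction of
#' macroinvertebrate AEC mass that carried trait data. A high KSI means
#' the web's most influential invertebrates are also the most
#' disturbance-sensitive.
#'
#' @param aec named AEC vector over all web nodes (see
#'   [environ_centrality]); only macroinvertebrate entries enter Eq. form.
#' @param guilds named character vector (or factor) giving each node's
#'   guild; nodes with guild "invertebrate" are the index's scope.
#' @param scores named per-taxon sensitivity scores; `NA` = missing.
#' @return list with `ksi` and `coverage`.
#' @export
compute_ksi <- function(aec, guilds, scores) {
  guilds <- stats::setNames(as.character(guilds), names(guilds))
  inv <- names(aec)[!is.na(guilds[names(aec)]) &
                      guilds[names(aec)] == "invertebrate"]
  if (!length(inv)) stop("no macroinvertebrate nodes in the web")
  sc <- scores[inv]
  has <- !is.na(sc)
  denom_all <- sum(aec[inv])
  if (!any(has & aec[inv] > 0) || sum(aec[inv][has]) <= 0) {
    stop("no scored macroinvertebrate carries positive centrality")
  }
  num <- sum(sc[has] * aec[inv][has])
  den <- sum(aec[inv][has])
  list(ksi = num / den,
       coverage = if (denom_all > 0) den / denom_all else 0)
}

#' All five Keystone Sensitivity Indices for one web
#'
#' @param net a balanced [flow_network].
#' @param guilds named guild vector over the web's nodes (use
#'   "invertebrate" for macroinvertebrates).
#' @param traits trait table as in [score_traits].
#' @return data.frame with one row per trait category: trait, ksi,
#'   coverage.
#' @export
ksi_for_web <- function(net, guilds, traits) {
  aec <- environ_centrality(net)$AEC
  out <- lapply(trait_categories(), function(cat) {
    sc <- score_traits(traits, cat)
    res <- compute_ksi(aec, guilds, sc)
    data.frame(trait = cat, ksi = res$ksi, coverage = res$coverage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
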