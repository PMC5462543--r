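#' Taxonomy scheme for plastid-proteome reconstruction
#'
#' A taxonomy scheme maps sequence sub-categories to lineages, groups the
#' eleven ochrophyte sub-categories into the three major ochrophyte groups
#' (chrysista, hypogyristea, diatoms), and declares which lineages are
#' CASH lineages (secondary red plastids; excluded from outgroup searches)
#' and which are outgroup lineages (candidate evolutionary donors).
#'
#' @param sub_categories named character vector mapping sub-category name to
#'   lineage name.
#' @param ochrophyte_groups named list of character vectors partitioning the
#'   eleven ochrophyte sub-categories into `chrysista` (3), `hypogyristea`
#'   (3) and `diatoms` (5).
#' @param cash_lineages character vector of CASH lineage names.
#' @param outgroup_lineages character vector of donor/outgroup lineage names.
#'
#' @return An object of class `taxonomy_scheme`.
#' @seealso [default_taxonomy()]
#' @export
taxonomy_scheme <- function(sub_categories, ochrophyte_groups,
                            cash_lineages, outgroup_lineages) {
  stopifnot(is.character(sub_categories), !is.null(names(sub_categories)))
  if (anyDuplicated(names(sub_categories)))
    stop("sub-category names must be unique")
  groups <- unlist(ochrophyte_groups, use.names = FALSE)
  if (anyDuplicated(groups))
    stop("ochrophyte groups must be disjoint")
  sizes <- lengths(ochrophyte_groups)
  if (!identical(sort(names(ochrophyte_groups)),
                 c("chrysista", "diatoms", "hypogyristea")))
    stop("ochrophyte groups must be chrysista, hypogyristea and diatoms")
  if (sizes[["chrysista"]] != 3L || sizes[["hypogyristea"]] != 3L ||
      sizes[["diatoms"]] != 5L)
    stop("ochrophyte groups must have sizes 3 (chrysista), 3 (hypogyristea), 5 (diatoms)")
  missing <- setdiff(groups, names(sub_categories))
  if (length(missing))
    stop("ochrophyte sub-categories not in sub_categories map: ",
         paste(missing, collapse = ", "))
  obj <- list(
    sub_categories    = sub_categories,
    lineages          = unique(unname(sub_categories)),
    ochrophyte_groups = ochrophyte_groups,
    cash_lineages     = cash_lineages,
    outgroup_lineages = outgroup_lineages
  )
  class(obj) <- "taxonomy_scheme"
  obj
}

#' Default taxonomy used throughout the package
#'
#' Eleven ochrophyte sub-categories in three groups, three sub-categories for
#' each candidate donor lineage (red algae, green algae, aplastidic
#' stramenopiles, prokaryotes), smaller representations for other eukaryotes,
#' viruses and glaucophytes, and the CASH lineages (haptophytes with three
#' sub-categories, cryptomonads with two, dinotoms, other alveolates,
#' euglenids, chlorarachniophytes).
#'
#' @return A `taxonomy_scheme`.
#' @export
default_taxonomy <- function() {
  sub <- c(
    # ochrophytes: chrysista
    px_clade = "ochrophytes", raphidophytes = "ochrophytes",
    pesc_clade = "ochrophytes",
    # ochrophytes: hypogyristea
    pelagophytes = "ochrophytes", dictyochophytes = "ochrophytes",
    bolidophytes = "ochrophytes",
    # ochrophytes: diatoms
    corethron = "ochrophytes", radial_centrics = "ochrophytes",
    thalassiosirales = "ochrophytes", polar_centrics = "ochrophytes",
    pennates = "ochrophytes",
    # donor / outgroup lineages
    cyanidiales = "red_algae", florideophytes = "red_algae",
    porphyridiophytes = "red_algae",
    core_chlorophytes = "green_algae", prasinophytes = "green_algae",
    streptophytes = "green_algae",
    oomycetes = "aplastidic_stramenopiles",
    labyrinthulomycetes = "aplastidic_stramenopiles",
    slopalinids = "aplastidic_stramenopiles",
    cyanobacteria = "prokaryotes", actinobacteria = "prokaryotes",
    proteobacteria = "prokaryotes",
    opisthokonts = "other_eukaryotes", amoebozoa = "other_eukaryotes",
    ncldv = "viruses",
    glaucophytes_sc = "glaucophytes",
    # CASH and other secondary lineages
    pavlovophytes = "haptophytes", prymnesiales = "haptophytes",
    isochrysidales = "haptophytes",
    pyrenomonadales = "cryptomonads", cryptomonadales = "cryptomonads",
    dinotoms_sc = "dinotoms",
    dinoflagellates = "other_alveolates", apicomplexans = "other_alveolates",
    euglenids_sc = "euglenids",
    chlorarachniophytes_sc = "chlorarachniophytes"
  )
  taxonomy_scheme(
    sub_categories = sub,
    ochrophyte_groups = list(
      chrysista    = c("px_clade", "raphidophytes", "pesc_clade"),
      hypogyristea = c("pelagophytes", "dictyochophytes", "bolidophytes"),
      diatoms      = c("corethron", "radial_centrics", "thalassiosirales",
                       "polar_centrics", "pennates")
    ),
    cash_lineages = c("cryptomonads", "haptophytes", "dinotoms",
                      "other_alveolates", "euglenids", "chlorarachniophytes"),
    outgroup_lineages = c("red_algae", "green_algae",
                          "aplastidic_stramenopiles", "other_eukaryotes",
                          "prokaryotes", "viruses")
  )
}

#' Lineage of a sub-category
#'
#' @param sub_category character vector of sub-category names.
#' @param taxonomy a `taxonomy_scheme`.
#' @param ochrophyte_as_group if `TRUE`, ochrophyte sub-categories are
#'   reported as their group (`chrysista`, `hypogyristea`, `diatoms`) rather
#'   than as `ochrophytes`; used by the CASH-lineage analyses, which treat
#'   the three ochrophyte groups as separate lineages.
#' @return character vector of lineage names (NA for unknown sub-categories).
#' @export
lineage_of <- function(sub_category, taxonomy = default_taxonomy(),
                       ochrophyte_as_group = FALSE) {
  lin <- unname(taxonomy$sub_categories[sub_category])
  if (ochrophyte_as_group) {
    for (g in names(taxonomy$ochrophyte_groups)) {
      lin[sub_category %in% taxonomy$ochrophyte_groups[[g]]] <- g
    }
  }
  lin
}

#' Ochrophyte group of a sub-category
#'
#' @inheritParams lineage_of
#' @return group name (`chrysista`/`hypogyristea`/`diatoms`) or NA.
#' @export
ochrophyte_group_of <- function(sub_category, taxonomy = default_taxonomy()) {
  out <- rep(NA_character_, length(sub_category))
  for (g in names(taxonomy$ochrophyte_groups)) {
    out[sub_category %in% taxonomy$ochrophyte_groups[[g]]] <- g
  }
  out
}

#' Is a sub-category an ochrophyte sub-category?
#' @inheritParams lineage_of
#' @return logical vector.
#' @export
is_ochrophyte <- function(sub_category, taxonomy = default_taxonomy()) {
  sub_category %in% unlist(taxonomy$ochrophyte_groups, use.names = FALSE)
}

#' @export
print.taxonomy_scheme <- function(x, ...) {
  cat("taxonomy_scheme:", length(x$sub_categories), "sub-categories,",
      length(x$lineages), "lineages\n")
  cat("  ochrophyte groups:",
      paste(sprintf("%s(%d)", names(x$ochrophyte_groups),
                    lengths(x$ochrophyte_groups)), collapse = ", "), "\n")
  cat("  CASH lineages:", paste(x$cash_lineages, collapse = ", "), "\n")
  cat("  outgroup lineages:", paste(x$outgroup_lineages, collapse = ", "),
      "\n")
  invisible(x)
}
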