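#' Default brain parcellation label table
#'
#' Builds the default 113-region label table following the Harvard-Oxford
#' parcellation scheme: 48 cortical areas per hemisphere (96 labels) plus 17
#' subcortical entries (7 bilateral gray-matter structures, the brain stem and
#' the two lateral ventricles). Label ids are 1..113; 0 is reserved for
#' background.
#'
#' @return A data.frame with columns `label_id` (integer), `region_name`
#'   (character) and `hemisphere` (`"L"`, `"R"` or `""` for midline).
#' @export
default_label_table <- function() {
  cortical <- c(
    "Frontal pole", "Insular cortex", "Superior frontal gyrus",
    "Middle frontal gyrus", "Inferior frontal gyrus, pars triangularis",
    "Inferior frontal gyrus, pars opercularis", "Precentral gyrus",
    "Temporal pole", "Superior temporal gyrus, anterior division",
    "Superior temporal gyrus, posterior division",
    "Middle temporal gyrus, anterior division",
    "Middle temporal gyrus, posterior division",
    "Middle temporal gyrus, temporooccipital part",
    "Inferior temporal gyrus, anterior division",
    "Inferior temporal gyrus, posterior division",
    "Inferior temporal gyrus, temporooccipital part",
    "Postcentral gyrus", "Superior parietal lobule",
    "Supramarginal gyrus, anterior division",
    "Supramarginal gyrus, posterior division", "Angular gyrus",
    "Lateral occipital cortex, superior division",
    "Lateral occipital cortex, inferior division",
    "Intracalcarine cortex", "Frontal medial cortex",
    "Juxtapositional lobule cortex", "Subcallosal cortex",
    "Paracingulate gyrus", "Cingulate gyrus, anterior division",
    "Cingulate gyrus, posterior division", "Precuneous cortex",
    "Cuneal cortex", "Frontal orbital cortex",
    "Parahippocampal gyrus, anterior division",
    "Parahippocampal gyrus, posterior division", "Lingual gyrus",
    "Temporal fusiform cortex, anterior division",
    "Temporal fusiform cortex, posterior division",
    "Temporal occipital fusiform cortex", "Occipital fusiform gyrus",
    "Frontal operculum cortex", "Central opercular cortex",
    "Parietal operculum cortex", "Planum polare", "Heschl's gyrus",
    "Planum temporale", "Supracalcarine cortex", "Occipital pole"
  )
  stopifnot(length(cortical) == 48L)
  subcortical_bilateral <- c(
    "Thalamus", "Caudate", "Putamen", "Pallidum",
    "Hippocampus", "Amygdala", "Accumbens"
  )
  name <- c(
    cortical, cortical,
    subcortical_bilateral, subcortical_bilateral,
    "Lateral ventricle", "Lateral ventricle", "Brain stem"
  )
  hemi <- c(
    rep("L", 48L), rep("R", 48L),
    rep("L", 7L), rep("R", 7L),
    "L", "R", ""
  )
  data.frame(
    label_id = seq_along(name),
    region_name = name,
    hemisphere = hemi,
    stringsAsFactors = FALSE
  )
}

#' Read a label table from TSV
#'
#' Expects at least two columns, `label_id` and `region_name`; an optional
#' `hemisphere` column is carried through (empty otherwise).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame with columns `label_id`, `region_name`, `hemisphere`.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label_id", "region_name") %in% names(tab))) {
    stop("label table must have columns 'label_id' and 'region_name'")
  }
  tab$label_id <- as.integer(tab$label_id)
  if (anyNA(tab$label_id) || any(tab$label_id <= 0L)) {
    stop("label ids must be positive integers (0 is reserved for background)")
  }
  if (anyDuplicated(tab$label_id)) stop("duplicate label ids in table")
  if (is.null(tab$hemisphere)) tab$hemisphere <- ""
  tab[, c("label_id", "region_name", "hemisphere")]
}

#' Write a label table to TSV
#' @param table Label table data.frame.
#' @param path Output path.
#' @export
write_label_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region display names (name + hemisphere)
#' @param table Label table.
#' @return Character vector, one per row, e.g. "Hippocampus (R)".
#' @keywords internal
region_display_names <- function(table) {
  ifelse(table$hemisphere == "", table$region_name,
         paste0(table$region_name, " (", table$hemisphere, ")"))
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with columns `subject_id`, `volume_path` and `group`.
#' Volume paths are interpreted relative to the manifest's directory unless
#' absolute.
#'
#' @param path Manifest TSV path.
#' @param groups Allowed group labels (default `c("CN", "MCI", "AD")`).
#' @return data.frame with absolute `volume_path`.
#' @export
read_manifest <- function(path, groups = c("CN", "MCI", "AD")) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "volume_path", "group")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(man$group), groups)
  if (length(bad)) {
    stop("manifest contains groups outside the configured vocabulary: ",
         paste(bad, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$volume_path)
  man$volume_path[rel] <- file.path(dirname(path), man$volume_path[rel])
  man
}
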