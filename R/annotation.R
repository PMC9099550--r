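#' Default protein classification rules
#'
#' The cascade that assigns each protein an origin (`cellular`,
#' `serum/plasma`, or `unknown`) and a category works through annotation
#' layers in a fixed order: transmembrane/intramembrane flags combined with
#' subcellular location first, then decisive GO cellular-component terms,
#' then GO biological-process terms, and finally tissue specificity, keywords
#' and description text. The original adjudication was manual; this rule set
#' captures it as an editable configuration, so any term table can be
#' substituted.
#'
#' @return A named list of term tables used by [classify_protein()]:
#'   `membrane_locations`, `cc_map`, `bp_map`, `fallback_map` (each mapping a
#'   category to matching terms), and `serum_subcategories` mapping
#'   serum/plasma factor categories to keywords.
#' @export
annotation_rules <- function() {
  list(
    membrane_locations = c("cell membrane", "plasma membrane", "membrane"),
    cc_map = list(
      "cell membrane" = c("plasma membrane", "cell membrane",
                          "caveola", "membrane raft"),
      "cell part" = c("cytoplasm", "cytosol", "nucleus", "nucleoplasm",
                      "mitochondrion", "endoplasmic reticulum",
                      "golgi apparatus", "endosome", "lysosome",
                      "cytoskeleton", "ribosome", "organelle",
                      "intracellular"),
      "cell surface" = c("cell surface", "extracellular matrix",
                         "basement membrane"),
      "serum/plasma" = c("extracellular region", "extracellular space",
                         "blood plasma")
    ),
    bp_map = list(
      "cell part" = c("translation", "metabolic process", "cell cycle",
                      "intracellular signal transduction",
                      "cytoskeleton organization"),
      "serum/plasma" = c("complement activation", "blood coagulation",
                         "fibrinolysis", "acute-phase response",
                         "innate immune response in plasma")
    ),
    fallback_map = list(
      "serum/plasma" = c("secreted", "plasma", "serum"),
      "cell part" = c("cytoplasm", "cytoplasmic"),
      "cell membrane" = c("transmembrane", "membrane protein")
    ),
    serum_subcategories = list(
      "apolipoprotein" = c("apolipoprotein", "lipoprotein particle"),
      "coagulation factor" = c("coagulation", "thrombin", "fibrinogen",
                               "hemostasis", "antithrombin"),
      "complement factor" = c("complement"),
      "immunoglobulin" = c("immunoglobulin", "antibody", "ig gamma",
                           "ig kappa", "ig lambda", "ig heavy", "ig light")
    )
  )
}

#' Default cell-type marker map
#'
#' Maps CD-marker labels (plus `HSPG2` as the endothelial marker) to the cell
#' types they indicate. Markers specific to several cell types are listed
#' under each, so per-cell-type tallies intentionally do not sum to the
#' number of distinct markers.
#'
#' @return Named list: marker label -> character vector of cell types.
#' @export
cell_marker_map <- function() {
  list(
    CD14 = c("Monocyte/Macrophage"),
    CD40 = c("B cell", "Monocyte/Macrophage", "Endothelial cell"),
    CD41 = c("Platelet"),
    CD62P = c("Platelet", "Endothelial cell"),
    CD81 = c("Endothelial cell", "Monocyte/Macrophage", "Dendritic cell",
             "T cell", "B cell", "Granulocyte"),
    CD102 = c("NK cell", "Endothelial cell", "T cell",
              "Monocyte/Macrophage", "B cell"),
    CD233 = c("Erythrocyte"),
    HSPG2 = c("Endothelial cell")
  )
}

.split_terms <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x))
    return(character(0))
  tolower(trimws(strsplit(x, ";", fixed = TRUE)[[1]]))
}

.match_terms <- function(terms, table) {
  # category whose term list intersects `terms`; first category wins
  for (cat in names(table))
    if (any(terms %in% tolower(table[[cat]]))) return(cat)
  NA_character_
}

.match_text <- function(text, table) {
  text <- tolower(paste(text, collapse = " "))
  if (!nzchar(trimws(text))) return(NA_character_)
  for (cat in names(table))
    for (kw in tolower(table[[cat]]))
      if (grepl(kw, text, fixed = TRUE)) return(cat)
  NA_character_
}

#' Classify one protein into origin and category
#'
#' Applies the annotation cascade (see [annotation_rules()]): membrane
#' annotations with a membrane location give `cell membrane`; otherwise
#' decisive GO:CC terms, then GO:BP terms, then tissue specificity, keywords
#' and description decide among `cell membrane`, `cell part`, `cell surface`
#' and `serum/plasma`. Serum/plasma proteins are further assigned to
#' `apolipoprotein`, `coagulation factor`, `complement factor`,
#' `immunoglobulin` or `other` by keyword. If no rule fires the protein is
#' `unknown` -- a valid outcome, not an error.
#'
#' @param rec A one-row `data.frame` (or named list) with fields
#'   `protein_id`, `has_transmembrane`, `subcellular_locations`, `go_cc`,
#'   `go_bp`, `keywords`, `tissue_specificity`, `description` (set-valued
#'   fields `;`-delimited strings; missing fields treated as empty).
#' @param rules Rule tables, by default [annotation_rules()].
#' @return Named character vector `c(origin = ..., category = ...)`.
#' @export
classify_protein <- function(rec, rules = annotation_rules()) {
  g <- function(f) if (!is.null(rec[[f]])) rec[[f]] else NA_character_
  locs <- .split_terms(g("subcellular_locations"))
  cat <- NA_character_
  if (isTRUE(as.logical(rec[["has_transmembrane"]])) &&
      any(vapply(tolower(rules$membrane_locations),
                 function(m) any(grepl(m, locs, fixed = TRUE)), logical(1))))
    cat <- "cell membrane"
  if (is.na(cat)) cat <- .match_terms(.split_terms(g("go_cc")), rules$cc_map)
  if (is.na(cat)) cat <- .match_terms(.split_terms(g("go_bp")), rules$bp_map)
  if (is.na(cat))
    cat <- .match_text(c(g("tissue_specificity"), g("keywords"),
                         g("description")), rules$fallback_map)
  if (is.na(cat)) return(c(origin = "unknown", category = "unknown"))
  if (cat == "serum/plasma") {
    sub <- .match_text(c(g("keywords"), g("description"), g("go_bp"),
                         g("subcellular_locations")),
                       rules$serum_subcategories)
    if (is.na(sub)) sub <- "other"
    return(c(origin = "serum/plasma", category = sub))
  }
  c(origin = "cellular", category = cat)
}

#' Classify a table of proteins
#'
#' @param records `data.frame` of annotation records (one protein per row).
#' @inheritParams classify_protein
#' @return `records` with `origin` and `category` columns appended.
#' @export
classify_proteins <- function(records, rules = annotation_rules()) {
  cls <- t(vapply(seq_len(nrow(records)),
                  function(i) classify_protein(records[i, , drop = FALSE],
                                               rules),
                  character(2)))
  records$origin <- cls[, 1]
  records$category <- cls[, 2]
  records
}

#' Read an annotation table
#'
#' TSV with columns named as the annotation-record fields; set-valued fields
#' are `;`-delimited.
#'
#' @param path TSV path.
#' @return `data.frame` of annotation records.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(d) || any(!nzchar(d$protein_id)))
    stop("annotation table needs non-empty protein_id values", call. = FALSE)
  d
}

#' Detected protein sets per data slice
#'
#' A protein group counts as detected in a plasma-type/transport slice when
#' it was seen in at least two of the three technical replicates of at least
#' one donor of that slice. Slice-level sets are combined into per-plasma
#' sets, the overall set, and the unique-to-PFP / unique-to-PPP sets
#' (detected in one plasma type and in no sample of the other).
#'
#' @param detections Long `data.frame` with columns `protein`, `donor`,
#'   `plasma` (`"PFP"`/`"PPP"`), `transport` (`"C"`/`"PTS"`), `replicate`,
#'   and logical `detected`.
#' @param min_replicates Minimum replicates a protein must be seen in
#'   (default 2).
#' @param n_replicates Expected technical replicates per donor and slice
#'   (default 3); a different observed count is a configuration error unless
#'   `allow_any_replicates = TRUE`.
#' @param allow_any_replicates Skip the triplicate-structure check.
#' @return Named list of character vectors: `PFP_C`, `PFP_PTS`, `PPP_C`,
#'   `PPP_PTS`, `PFP`, `PPP`, `combined`, `unique_to_PFP`, `unique_to_PPP`.
#' @export
detection_filter <- function(detections, min_replicates = 2,
                             n_replicates = 3,
                             allow_any_replicates = FALSE) {
  need <- c("protein", "donor", "plasma", "transport", "replicate",
            "detected")
  if (!all(need %in% names(detections)))
    stop("detections must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!allow_any_replicates) {
    reps <- stats::aggregate(
      replicate ~ donor + plasma + transport, data = detections,
      FUN = function(r) length(unique(r)))
    if (any(reps$replicate != n_replicates))
      stop("replicate structure is not ", n_replicates,
           " technical replicates per donor and slice; set ",
           "allow_any_replicates = TRUE to override", call. = FALSE)
  }
  slice_set <- function(pl, tr) {
    d <- detections[detections$plasma == pl & detections$transport == tr &
                      detections$detected, , drop = FALSE]
    if (!nrow(d)) return(character(0))
    cnt <- stats::aggregate(detected ~ protein + donor, data = d, FUN = length)
    sort(unique(cnt$protein[cnt$detected >= min_replicates]))
  }
  s <- list(PFP_C = slice_set("PFP", "C"), PFP_PTS = slice_set("PFP", "PTS"),
            PPP_C = slice_set("PPP", "C"), PPP_PTS = slice_set("PPP", "PTS"))
  s$PFP <- sort(union(s$PFP_C, s$PFP_PTS))
  s$PPP <- sort(union(s$PPP_C, s$PPP_PTS))
  s$combined <- sort(union(s$PFP, s$PPP))
  # "unique to" excludes any detection event in the other plasma type
  seen <- function(pl) unique(
    detections$protein[detections$plasma == pl & detections$detected])
  s$unique_to_PFP <- sort(setdiff(s$PFP, seen("PPP")))
  s$unique_to_PPP <- sort(setdiff(s$PPP, seen("PFP")))
  s
}

#' Cross-tabulate protein classes over data slices
#'
#' Builds the origin-by-category tally for every detected-set slice, plus
#' cell-type marker counts. Totals are always computed from the category
#' rows, never stored independently.
#'
#' @param records Annotation `data.frame`; classified on the fly if it lacks
#'   `origin`/`category` columns.
#' @param detected_sets Named list of protein-id sets, e.g. from
#'   [detection_filter()].
#' @param rules Classification rules for unclassified records.
#' @param marker_map Marker-to-cell-type map, default [cell_marker_map()].
#' @return Object of class `class_tally`: list with `counts` (data.frame
#'   origin, category, one column per slice) and `markers` (cell type by
#'   slice data.frame).
#' @export
tally <- function(records, detected_sets, rules = annotation_rules(),
                  marker_map = cell_marker_map()) {
  if (!all(c("origin", "category") %in% names(records)))
    records <- classify_proteins(records, rules)
  miss <- setdiff(unique(unlist(detected_sets)), records$protein_id)
  if (length(miss))
    stop("detected proteins without annotation record: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  cats <- data.frame(
    origin = c(rep("cellular", 3), rep("serum/plasma", 5), "unknown"),
    category = c("cell membrane", "cell part", "cell surface",
                 "apolipoprotein", "coagulation factor", "complement factor",
                 "immunoglobulin", "other", "unknown"),
    stringsAsFactors = FALSE)
  counts <- cats
  for (sl in names(detected_sets)) {
    r <- records[records$protein_id %in% detected_sets[[sl]], , drop = FALSE]
    counts[[sl]] <- mapply(function(o, ct)
      sum(r$origin == o & r$category == ct), cats$origin, cats$category)
  }
  markers <- NULL
  if (!is.null(records$cd_marker)) {
    types <- sort(unique(unlist(marker_map)))
    markers <- data.frame(cell_type = c(types, "Total markers"),
                          stringsAsFactors = FALSE)
    for (sl in names(detected_sets)) {
      r <- records[records$protein_id %in% detected_sets[[sl]], ,
                   drop = FALSE]
      labs <- r$cd_marker[!is.na(r$cd_marker) & r$cd_marker %in%
                            names(marker_map)]
      per_type <- vapply(types, function(tp)
        sum(vapply(labs, function(l) tp %in% marker_map[[l]], logical(1))),
        numeric(1))
      markers[[sl]] <- c(per_type, length(unique(labs)))
    }
  }
  structure(list(counts = counts, markers = markers), class = "class_tally")
}

#' Totals of a class tally
#'
#' @param x A `class_tally` (or its `counts` data.frame).
#' @return `data.frame` with rows `total cellular`, `total serum/plasma`,
#'   `unknown`, and `total`, one column per slice, each computed as the sum
#'   of its category rows.
#' @export
tally_totals <- function(x) {
  counts <- if (inherits(x, "class_tally")) x$counts else x
  slices <- setdiff(names(counts), c("origin", "category"))
  rowset <- function(o) colSums(counts[counts$origin == o, slices,
                                       drop = FALSE])
  out <- rbind("total cellular" = rowset("cellular"),
               "total serum/plasma" = rowset("serum/plasma"),
               "unknown" = rowset("unknown"))
  out <- rbind(out, total = colSums(out))
  as.data.frame(out)
}

#' @export
print.class_tally <- function(x, ...) {
  cat("class_tally\n")
  print(x$counts, row.names = FALSE)
  tot <- tally_totals(x)
  print(tot)
  invisible(x)
}

#' Platelet-specific contamination ratio
#'
#' Percentage of a protein set that carries the platelet-proteome
#' annotation, reported to one decimal as in contamination summaries
#' (e.g. 393 platelet proteins among the 456 proteins unique to
#' platelet-poor plasma gives 86.2).
#'
#' @param count Number of platelet-specific proteins in the set.
#' @param size Size of the set (> 0).
#' @return Percentage rounded to one decimal.
#' @export
platelet_ratio <- function(count, size) {
  if (!is.numeric(size) || size <= 0)
    stop("set size must be positive", call. = FALSE)
  if (count < 0 || count > size)
    stop("count must lie in [0, size]", call. = FALSE)
  round(100 * count / size, 1)
}

#' Write a tally as TSV
#'
#' @param x A `class_tally`.
#' @param path Output path.
#' @export
write_tally_tsv <- function(x, path) {
  counts <- x$counts
  tot <- tally_totals(x)
  tot_df <- data.frame(origin = "", category = rownames(tot), tot,
                       check.names = FALSE)
  utils::write.table(rbind(counts, tot_df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
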