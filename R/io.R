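#' Write and read a cortical dataset as delimited text
#'
#' A dataset is stored as a directory of tab-separated tables:
#' `thickness.tsv` (rows = participants, columns = regions, first column the
#' participant id), `participants.tsv` (id, age, sex), `regions.tsv`
#' (region_id, hemisphere, centroid x/y/z, sphere sx/sy/sz, module), one
#' `mt_<depth>.tsv` per MT depth, and `ground_truth.yaml` when ground truth
#' is present.
#'
#' @param cohort a `cortical_cohort`.
#' @param path directory to create/populate.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the reconstructed `cortical_cohort`.
#' @export
write_dataset <- function(cohort, path) {
  stopifnot(inherits(cohort, "cortical_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_matrix <- function(m, file) {
    df <- data.frame(id = cohort$participants$id, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(path, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_matrix(cohort$thickness, "thickness.tsv")
  utils::write.table(cohort$participants, file.path(path, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cohort$regions),
                     file.path(path, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(cohort$mt)) {
    write_matrix(cohort$mt[[d]], paste0("mt_", gsub("[^A-Za-z0-9]", "", d),
                                        ".tsv"))
  }
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$mt_slope <- if (is.null(gt$mt_slope)) NULL else {
      c(list(.depths = colnames(gt$mt_slope)),
        as.list(as.data.frame(gt$mt_slope)))
    }
    if (!is.null(cohort$mt)) gt$mt_depths <- names(cohort$mt)
    yaml::write_yaml(gt, file.path(path, "ground_truth.yaml"),
                     precision = 15L)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need <- file.path(path, c("thickness.tsv", "participants.tsv",
                            "regions.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("dataset at ", path, " is missing: ",
         paste(basename(missing), collapse = ", "))
  }
  read_tsv <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                            header = TRUE, check.names = FALSE,
                                            stringsAsFactors = FALSE)
  participants <- read_tsv("participants.tsv")
  if (!"age" %in% names(participants)) {
    stop("participants table lacks an 'age' column")
  }
  bad_age <- which(!is.finite(participants$age))
  if (length(bad_age)) {
    stop("participant(s) lacking a valid age at row(s) ",
         paste(bad_age, collapse = ", "), ": ",
         paste(participants$id[bad_age], collapse = ", "))
  }
  regions <- read_tsv("regions.tsv")
  class(regions) <- c("region_set", "data.frame")

  read_matrix <- function(f) {
    df <- read_tsv(f)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- NULL
    if (ncol(m) != nrow(regions)) {
      stop("dimension mismatch in ", f, ": ", ncol(m),
           " region columns vs ", nrow(regions), " region metadata rows")
    }
    if (nrow(m) != nrow(participants)) {
      stop("dimension mismatch in ", f, ": ", nrow(m),
           " rows vs ", nrow(participants), " participants")
    }
    m
  }
  thickness <- read_matrix("thickness.tsv")

  mt <- NULL
  gt <- NULL
  gt_file <- file.path(path, "ground_truth.yaml")
  if (file.exists(gt_file)) {
    gt <- yaml::read_yaml(gt_file)
    for (f in c("ct_baseline", "ct_slope", "loadings", "planted_module",
                "age_range")) {
      if (!is.null(gt[[f]])) gt[[f]] <- as.numeric(unlist(gt[[f]]))
    }
    if (!is.null(gt$mt_slope)) {
      depths <- unlist(gt$mt_slope$.depths)
      gt$mt_slope <- do.call(
        cbind, lapply(gt$mt_slope[depths], as.numeric))
      colnames(gt$mt_slope) <- depths
    }
    if (!is.null(gt$mt_depths)) {
      depths <- unlist(gt$mt_depths)
      mt <- lapply(depths, function(d) {
        read_matrix(paste0("mt_", gsub("[^A-Za-z0-9]", "", d), ".tsv"))
      })
      names(mt) <- depths
    }
  }

  structure(list(thickness = thickness, participants = participants,
                 regions = regions, mt = mt, ground_truth = gt),
            class = "cortical_cohort")
}
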