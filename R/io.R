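#' Write a synthetic study to disk
#'
#' Plain-text layout: one timeseries TSV per subject (frames x parcels,
#' header = parcel ids), covariates CSV, parcel metadata CSV (parcel_id,
#' label, x, y, z), optional behavior CSV and annotation-map CSVs, and a
#' manifest JSON recording the configuration and seed.
#'
#' @param study list from [simulate_study] (optionally with `$behavior`
#'   and `$maps` added)
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  pid <- sprintf("p%03d", seq_along(study$labels))
  for (sid in names(study$ts$subjects)) {
    m <- study$ts$subjects[[sid]]
    colnames(m) <- pid
    write.table(format(m, digits = 8), file.path(dir, "timeseries", paste0(sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.csv(data.frame(subject = names(study$ts$group), group = study$ts$group),
            file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(cbind(subject = names(study$ts$group)[study$ts$group == "patient"],
                  study$covariates),
            file.path(dir, "covariates.csv"), row.names = FALSE)
  write.csv(data.frame(parcel_id = pid, label = study$labels,
                       x = study$coords[, 1], y = study$coords[, 2],
                       z = study$coords[, 3]),
            file.path(dir, "parcels.csv"), row.names = FALSE)
  if (!is.null(study$behavior))
    write.csv(cbind(subject = rownames(study$behavior), as.data.frame(study$behavior)),
              file.path(dir, "behavior.csv"), row.names = FALSE)
  if (!is.null(study$maps)) {
    dir.create(file.path(dir, "maps"), showWarnings = FALSE)
    for (nm in names(study$maps))
      write.csv(data.frame(parcel_id = pid[seq_along(study$maps[[nm]])],
                           value = study$maps[[nm]]),
                file.path(dir, "maps", paste0(nm, ".csv")), row.names = FALSE)
  }
  manifest <- list(config = unclass(study$cfg),
                   plan = unclass(study$plan),
                   tr = study$ts$tr,
                   n_subjects = length(study$ts$subjects),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study]
#'
#' @param dir study directory
#' @return list with `ts`, `covariates`, `labels`, `coords`, and (when
#'   present) `behavior`, `maps`, `cfg`, `plan`
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  subs <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  mats <- lapply(subs$subject, function(sid)
    as.matrix(read.delim(file.path(dir, "timeseries", paste0(sid, ".tsv")))))
  names(mats) <- subs$subject
  parcels <- read.csv(file.path(dir, "parcels.csv"), stringsAsFactors = FALSE)
  ts <- parcel_ts_set(mats, tr = manifest$tr, group = subs$group,
                      parcel_ids = parcels$parcel_id)
  cov <- read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  out <- list(ts = ts, covariates = cov[, setdiff(names(cov), "subject")],
              labels = parcels$label,
              coords = as.matrix(parcels[, c("x", "y", "z")]),
              cfg = manifest$config, plan = manifest$plan)
  beh_path <- file.path(dir, "behavior.csv")
  if (file.exists(beh_path)) {
    beh <- read.csv(beh_path, stringsAsFactors = FALSE)
    rn <- beh$subject
    beh <- as.matrix(beh[, setdiff(names(beh), "subject")])
    rownames(beh) <- rn
    out$behavior <- beh
  }
  map_dir <- file.path(dir, "maps")
  if (dir.exists(map_dir)) {
    files <- list.files(map_dir, pattern = "\\.csv$", full.names = TRUE)
    out$maps <- lapply(files, function(f) read.csv(f)$value)
    names(out$maps) <- sub("\\.csv$", "", basename(files))
  }
  out
}

#' Write an entropy stack to CSV
#'
#' Group stack (subjects x edges) with subject ids in the first column.
#'
#' @param es an `entropy_set`
#' @param path output CSV path
#' @export
write_entropy_csv <- function(es, path) {
  write.csv(cbind(subject = rownames(es$values), as.data.frame(es$values)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as CSV with subject-id header
#'
#' @param sim a `similarity_matrix` from [build_similarity]
#' @param path output CSV path
#' @export
write_similarity_csv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  write.csv(as.data.frame(sim$R), path, row.names = TRUE)
  invisible(path)
}

#' Write a template mask as an edge-list CSV
#'
#' @param mask a [template_mask]
#' @param eidx the [edge_index] of the study
#' @param path output CSV path
#' @export
write_template_csv <- function(mask, eidx, path) {
  write.csv(data.frame(edge_id = mask$edges,
                       parcel_i = eidx$i[mask$edges],
                       parcel_j = eidx$j[mask$edges]),
            path, row.names = FALSE)
  invisible(path)
}
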