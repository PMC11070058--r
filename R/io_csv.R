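#' Write lineage records to CSV
#'
#' Header `frame,tree_id,branch_id,parent_branch_id,instance_id,centroid_x,
#' centroid_y,area,raw_class,smoothed_class,is_gap_fill`; one row per node,
#' deterministic `(frame, tree_id, branch_id)` ordering; missing values
#' written as empty fields.
#'
#' @param records `data.frame` from [export_lineage()] (or a
#'   `track_forest`, exported on the fly).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lineage_csv <- function(records, path) {
  if (inherits(records, "track_forest")) records <- export_lineage(records)
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   quote = which(names(records) %in%
                                 c("raw_class", "smoothed_class")))
  invisible(path)
}

#' Read a lineage CSV
#'
#' @param path file written by [write_lineage_csv()] (or any CSV with the
#'   same columns, e.g. from another tracker).
#' @return `data.frame` of lineage records.
#' @export
read_lineage_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           frame = "integer", tree_id = "integer",
                           branch_id = "integer",
                           parent_branch_id = "integer",
                           instance_id = "integer",
                           centroid_x = "numeric", centroid_y = "numeric",
                           area = "numeric", raw_class = "character",
                           smoothed_class = "character",
                           is_gap_fill = "logical"))
  out$raw_class[!is.na(out$raw_class) & out$raw_class == ""] <- NA_character_
  out$smoothed_class[!is.na(out$smoothed_class) &
                     out$smoothed_class == ""] <- NA_character_
  out
}

# lineage records -> evaluation tracks (per branch). Detections carry only
# (frame, instance_id, centroid), so metric correspondence uses mode "id".
tracks_from_records <- function(records) {
  records <- records[!records$is_gap_fill, , drop = FALSE]
  out <- list()
  for (bid in sort(unique(records$branch_id))) {
    rows <- records[records$branch_id == bid, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    out[[as.character(bid)]] <- list(
      id = bid, frames = rows$frame,
      cells = lapply(seq_len(nrow(rows)), function(k)
        list(frame = rows$frame[k], instance_id = rows$instance_id[k],
             centroid = c(rows$centroid_x[k], rows$centroid_y[k]),
             area = rows$area[k],
             class_label = rows$raw_class[k],
             smoothed_class = rows$smoothed_class[k])))
  }
  out
}

# division events from lineage records: a parent branch with exactly two
# child branches
divisions_from_records <- function(records) {
  kids <- unique(records[!is.na(records$parent_branch_id),
                         c("branch_id", "parent_branch_id")])
  out <- list()
  for (pid in sort(unique(kids$parent_branch_id))) {
    ids <- sort(kids$branch_id[kids$parent_branch_id == pid])
    if (length(ids) != 2) next
    f <- min(records$frame[records$branch_id == ids[1]])
    out[[length(out) + 1L]] <- list(frame = f, mother_branch = pid,
                                    daughters = ids)
  }
  out
}
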