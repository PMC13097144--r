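WELL_ROLES <- c("compound", "dmso_positive", "cd4_only_negative", "unstained")

#' Well coordinates of a 384-well plate
#'
#' @param order `"row_major"` (A1, A2, ..., A24, B1, ...) or `"serpentine"`
#'   (even rows reversed).
#' @return character vector of 384 well names.
#' @export
well_names_384 <- function(order = c("row_major", "serpentine")) {
  order <- match.arg(order)
  rows <- LETTERS[1:16]
  out <- character(0)
  for (r in seq_along(rows)) {
    cols <- 1:24
    if (order == "serpentine" && r %% 2L == 0L) cols <- rev(cols)
    out <- c(out, paste0(rows[r], cols))
  }
  out
}

#' Construct a 384-well screening plate layout
#'
#' By default the last column (24) carries the controls: 8 DMSO-treated
#' positive-control wells (CD4 + FoxP3 stained), 4 CD4-only negative-control
#' wells and 4 unstained wells -- the minimum control complement of the
#' screen design. All remaining wells are compound wells.
#'
#' @param plate_id plate identifier.
#' @param compound_ids compound identifiers for the compound wells (recycled
#'   names are not allowed); defaults to `C0001...`. May be shorter than the
#'   number of available compound wells, in which case the surplus wells are
#'   dropped from the layout.
#' @param concentration_um screening concentration in micromolar (default 10).
#' @param n_dmso,n_cd4only,n_unstained control well counts.
#' @param order acquisition order, see [well_names_384()].
#' @return a `plate_layout`: data.frame with columns `plate_id`, `well`,
#'   `role`, `compound_id`, `concentration_um`, ordered by acquisition order.
#' @export
plate_layout_default <- function(plate_id = "plate1", compound_ids = NULL,
                                 concentration_um = 10,
                                 n_dmso = 8, n_cd4only = 4, n_unstained = 4,
                                 order = "row_major") {
  wells <- well_names_384(order)
  ctrl_col <- 24L
  ctrl_wells <- paste0(LETTERS[1:16], ctrl_col)
  n_ctrl <- n_dmso + n_cd4only + n_unstained
  if (n_ctrl > length(ctrl_wells))
    stopf("control wells (%d) exceed one column (16)", n_ctrl)
  roles <- setNames(rep("compound", length(wells)), wells)
  roles[ctrl_wells[seq_len(n_dmso)]] <- "dmso_positive"
  roles[ctrl_wells[n_dmso + seq_len(n_cd4only)]] <- "cd4_only_negative"
  roles[ctrl_wells[n_dmso + n_cd4only + seq_len(n_unstained)]] <- "unstained"
  cmp_wells <- wells[roles[wells] == "compound"]
  if (is.null(compound_ids))
    compound_ids <- sprintf("C%04d", seq_along(cmp_wells))
  if (length(compound_ids) > length(cmp_wells))
    stopf("more compound ids (%d) than compound wells (%d)",
          length(compound_ids), length(cmp_wells))
  keep_cmp <- cmp_wells[seq_along(compound_ids)]
  drop <- setdiff(cmp_wells, keep_cmp)
  wells <- setdiff(wells, drop)
  layout <- data.frame(
    plate_id = plate_id, well = wells, role = unname(roles[wells]),
    compound_id = NA_character_, concentration_um = NA_real_,
    stringsAsFactors = FALSE)
  layout$compound_id[match(keep_cmp, layout$well)] <- compound_ids
  layout$concentration_um[layout$role == "compound"] <- concentration_um
  validate_plate_layout(layout)
}

#' Read / write a plate layout CSV
#'
#' Columns: `well`, `role`, `compound_id`, `concentration_um` and optionally
#' `plate_id`.
#'
#' @param path CSV path.
#' @param plate_id plate id used if the CSV has no `plate_id` column.
#' @return a validated `plate_layout` data.frame.
#' @export
read_plate_layout <- function(path, plate_id = "plate1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$plate_id)) df$plate_id <- plate_id
  if (is.null(df$compound_id)) df$compound_id <- NA_character_
  if (is.null(df$concentration_um)) df$concentration_um <- NA_real_
  validate_plate_layout(df[c("plate_id", "well", "role", "compound_id",
                             "concentration_um")])
}

#' @rdname read_plate_layout
#' @param layout a `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

validate_plate_layout <- function(layout) {
  req <- c("plate_id", "well", "role")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stopf("layout missing column(s): %s", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role))
    stopf("unknown well role(s): %s (allowed: %s)",
          paste(bad_role, collapse = ", "), paste(WELL_ROLES, collapse = ", "))
  ok_well <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", layout$well)
  if (any(!ok_well))
    stopf("invalid 384-well coordinate(s): %s",
          paste(utils::head(layout$well[!ok_well], 5L), collapse = ", "))
  if (anyDuplicated(paste(layout$plate_id, layout$well)))
    stopf("duplicate wells in layout")
  no_id <- layout$role == "compound" & is.na(layout$compound_id)
  if (any(no_id))
    stopf("compound well(s) without compound_id: %s",
          paste(utils::head(layout$well[no_id], 5L), collapse = ", "))
  class(layout) <- c("plate_layout", "data.frame")
  layout
}
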