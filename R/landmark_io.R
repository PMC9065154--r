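# Landmark, slider-table, and lever-table input/output.
#
# A landmark dataset is a long tibble with one row per (specimen, landmark):
# columns `specimen`, `landmark` (1-based integer), `x`, `y`, and optional
# metadata columns `taxon`, `digit`, `clade_group`. All files use 1-based
# landmark indices; coordinates follow the lateral-view convention (proximal
# end left, dorsal up, y increasing dorsally). Readers never reorient;
# image-origin data can be mirrored with `flip_y = TRUE`.

#' Validate a landmark dataset
#'
#' Checks the invariants every landmark tibble must satisfy: a constant
#' number of landmarks per specimen, finite coordinates, positive centroid
#' size, and unique specimen identifiers.
#'
#' @param data Tibble with columns `specimen`, `landmark`, `x`, `y`.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_landmarks <- function(data) {
  need <- c("specimen", "landmark", "x", "y")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("landmark data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    bad <- unique(data$specimen[!is.finite(data$x) | !is.finite(data$y)])
    abort(paste0("non-finite coordinates for specimen(s): ",
                 paste(bad, collapse = ", ")))
  }
  ids <- unique(data$specimen)
  counts <- table(data$specimen)[ids]
  if (length(unique(as.integer(counts))) > 1) {
    k <- as.integer(counts[1])          # first specimen sets the expectation
    off <- names(counts)[counts != k]
    abort(paste0("ragged landmark counts (expected ", k, " per specimen): ",
                 paste(off, collapse = ", ")))
  }
  cs <- data |>
    summarise(cs = sqrt(sum((.data$x - mean(.data$x))^2 +
                            (.data$y - mean(.data$y))^2)),
              .by = "specimen")
  if (any(cs$cs <= 0)) {
    abort(paste0("degenerate configuration (centroid size 0): ",
                 paste(cs$specimen[cs$cs <= 0], collapse = ", ")))
  }
  invisible(data)
}

#' Number of landmarks per specimen
#' @param data A landmark tibble.
#' @return Integer K.
#' @export
landmarks_k <- function(data) {
  as.integer(unique(table(data$specimen)))[1]
}

# long tibble -> K x 2 x n array (specimen order = first appearance)
lmk_array <- function(data) {
  validate_landmarks(data)
  ids <- unique(data$specimen)
  k <- landmarks_k(data)
  arr <- array(NA_real_, dim = c(k, 2, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    sub <- data[data$specimen == ids[i], ]
    sub <- sub[order(sub$landmark), ]
    arr[, 1, i] <- sub$x
    arr[, 2, i] <- sub$y
  }
  arr
}

# K x 2 x n array -> long tibble, optionally re-attaching metadata
array_lmk <- function(arr, meta = NULL) {
  ids <- dimnames(arr)[[3]]
  k <- dim(arr)[1]
  out <- tibble(
    specimen = rep(ids, each = k),
    landmark = rep(seq_len(k), times = length(ids)),
    x = as.vector(apply(arr, 3, function(m) m[, 1])),
    y = as.vector(apply(arr, 3, function(m) m[, 2]))
  )
  if (!is.null(meta) && nrow(meta) > 0) {
    keep <- intersect(c("specimen", "taxon", "digit", "clade_group"), names(meta))
    out <- left_join(out, distinct(meta[keep]), by = "specimen")
  }
  out
}

# per-specimen metadata table from a landmark tibble (or NULL)
lmk_meta <- function(data) {
  keep <- intersect(c("specimen", "taxon", "digit", "clade_group"), names(data))
  if (length(keep) < 2) return(NULL)
  distinct(data[keep])
}

#' Read a TPS landmark file
#'
#' Parses the classic TPS format: each record has an `LM=K` line, K
#' whitespace-separated coordinate lines, an `ID=` line, and optionally a
#' `SCALE=` line whose factor is applied to the coordinates.
#'
#' @param path Path to a TPS file.
#' @param flip_y Mirror the y axis (for data digitized with an image-origin
#'   convention where y increases downwards).
#' @return A landmark tibble (`specimen`, `landmark`, `x`, `y`).
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  rec_no <- 0L
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      abort(paste0("line ", i, ": expected an LM= record header, got '", ln, "'"))
    }
    rec_no <- rec_no + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 1) abort(paste0("line ", i, ": invalid LM= count"))
    i <- i + 1L
    xy <- matrix(NA_real_, nrow = k, ncol = 2)
    for (j in seq_len(k)) {
      if (i > n_lines || grepl("^(LM|ID|SCALE|IMAGE)\\s*=", trimws(lines[i]),
                               ignore.case = TRUE)) {
        abort(paste0("record ", rec_no, ": LM=", k,
                     " but only ", j - 1L, " coordinate line(s) found"))
      }
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        abort(paste0("line ", i, ": non-numeric or malformed coordinate line"))
      }
      xy[j, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_
    scale <- NA_real_
    while (i <= n_lines && !grepl("^LM\\s*=", trimws(lines[i]), ignore.case = TRUE)) {
      ln2 <- trimws(lines[i])
      if (grepl("^ID\\s*=", ln2, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln2, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln2, ignore.case = TRUE)) {
        scale <- suppressWarnings(
          as.numeric(sub("^SCALE\\s*=\\s*", "", ln2, ignore.case = TRUE)))
        if (is.na(scale)) abort(paste0("line ", i, ": non-numeric SCALE="))
      } else if (ln2 != "" && !grepl("^IMAGE\\s*=", ln2, ignore.case = TRUE)) {
        abort(paste0("line ", i, ": unexpected content inside record ", rec_no))
      }
      i <- i + 1L
    }
    if (is.na(id)) abort(paste0("record ", rec_no, ": missing ID= line"))
    if (!is.na(scale)) xy <- xy * scale
    if (flip_y) xy[, 2] <- -xy[, 2]
    recs[[length(recs) + 1L]] <- tibble(
      specimen = id, landmark = seq_len(k), x = xy[, 1], y = xy[, 2])
  }
  out <- bind_rows(recs)
  ids_all <- map_chr(recs, ~ .x$specimen[1])
  if (anyDuplicated(ids_all)) {
    abort(paste0("duplicate specimen ID(s): ",
                 paste(unique(ids_all[duplicated(ids_all)]), collapse = ", ")))
  }
  validate_landmarks(out)
  out
}

#' Write a TPS landmark file
#'
#' @param data A landmark tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  validate_landmarks(data)
  ids <- unique(data$specimen)
  k <- landmarks_k(data)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    sub <- data[data$specimen == id, ]
    sub <- sub[order(sub$landmark), ]
    writeLines(c(paste0("LM=", k),
                 sprintf("%.17g %.17g", sub$x, sub$y),
                 paste0("ID=", id)), con)
  }
  invisible(path)
}

#' Read landmark coordinates from CSV
#'
#' Accepts two dialects. Long: one row per landmark with columns
#' `specimen,landmark,x,y`. Wide: one row per specimen with columns
#' `specimen,x1,y1,...,xK,yK`. Metadata columns (`taxon`, `digit`,
#' `clade_group`) are carried through when present in either dialect.
#'
#' @param path Path to a CSV file (header row required).
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @param flip_y Mirror the y axis.
#' @return A landmark tibble.
#' @export
read_landmark_csv <- function(path, format = c("auto", "long", "wide"),
                              flip_y = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "auto") {
    format <- if (all(c("landmark", "x", "y") %in% names(raw))) "long" else "wide"
  }
  meta_cols <- intersect(c("taxon", "digit", "clade_group"), names(raw))
  if (format == "long") {
    need <- c("specimen", "landmark", "x", "y")
    if (!all(need %in% names(raw))) {
      abort("long-format CSV needs columns specimen, landmark, x, y")
    }
    out <- raw |>
      mutate(specimen = as.character(.data$specimen),
             landmark = as.integer(.data$landmark)) |>
      select(all_of(c(need, meta_cols)))
  } else {
    if (!"specimen" %in% names(raw)) abort("wide-format CSV needs a specimen column")
    xcols <- grep("^x[0-9]+$", names(raw), value = TRUE)
    ycols <- grep("^y[0-9]+$", names(raw), value = TRUE)
    k <- length(xcols)
    if (k == 0 || length(ycols) != k) {
      abort("wide-format CSV needs matched x1..xK and y1..yK columns")
    }
    ord <- order(as.integer(sub("^x", "", xcols)))
    xcols <- xcols[ord]
    ycols <- paste0("y", sub("^x", "", xcols))
    out <- tibble(
      specimen = rep(as.character(raw$specimen), each = k),
      landmark = rep(seq_len(k), times = nrow(raw)),
      x = as.vector(t(as.matrix(raw[xcols]))),
      y = as.vector(t(as.matrix(raw[ycols])))
    )
    if (length(meta_cols) > 0) {
      out <- left_join(out,
                       mutate(raw[c("specimen", meta_cols)],
                              specimen = as.character(.data$specimen)),
                       by = "specimen")
    }
  }
  if (flip_y) out$y <- -out$y
  validate_landmarks(out)
  out
}

#' Write landmark coordinates to CSV
#'
#' @param data A landmark tibble.
#' @param path Output path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(data, path, format = c("long", "wide")) {
  format <- match.arg(format)
  validate_landmarks(data)
  if (format == "long") {
    readr::write_csv(data, path, progress = FALSE)
  } else {
    k <- landmarks_k(data)
    meta <- lmk_meta(data)
    arr <- lmk_array(data)
    wide <- as_tibble(t(apply(arr, 3, function(m) as.vector(t(m)))),
                      .name_repair = "minimal")
    names(wide) <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
    wide <- bind_cols(tibble(specimen = dimnames(arr)[[3]]), wide)
    if (!is.null(meta)) wide <- left_join(wide, meta, by = "specimen")
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Build a slider table
#'
#' A slider table designates which landmarks are semi-landmarks and the two
#' neighbors defining each one's tangent chord. Indices are 1-based.
#'
#' @param before,slide,after Integer vectors of equal length.
#' @param k Number of landmarks in the configurations the table applies to.
#' @return A tibble with columns `before`, `slide`, `after`.
#' @export
make_sliders <- function(before, slide, after, k) {
  tab <- tibble(before = as.integer(before),
                slide = as.integer(slide),
                after = as.integer(after))
  validate_sliders(tab, k)
}

#' @rdname make_sliders
#' @param sliders A candidate slider tibble.
#' @export
validate_sliders <- function(sliders, k) {
  if (nrow(sliders) == 0) {
    return(tibble(before = integer(), slide = integer(), after = integer()))
  }
  idx <- c(sliders$before, sliders$slide, sliders$after)
  if (any(idx < 1 | idx > k)) {
    abort(paste0("slider index out of range 1..", k, ": ",
                 paste(unique(idx[idx < 1 | idx > k]), collapse = ", ")))
  }
  if (anyDuplicated(sliders$slide)) {
    abort(paste0("repeated slider index: ",
                 paste(unique(sliders$slide[duplicated(sliders$slide)]),
                       collapse = ", ")))
  }
  bad <- sliders$slide == sliders$before | sliders$slide == sliders$after
  if (any(bad)) {
    abort(paste0("slider equals its own neighbor at row(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  sliders
}

#' Read a slider table from CSV
#'
#' Expects three integer columns `before,slide,after` (the column `slider`
#' is accepted as a synonym for `slide`). 1-based indices. An empty file
#' yields an empty table: all landmarks are then treated as fixed and GPA
#' degenerates to plain GPA.
#'
#' @param path Path to the CSV file.
#' @param k Number of landmarks per configuration.
#' @return A validated slider tibble.
#' @export
read_sliders <- function(path, k) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(tibble(before = integer(), slide = integer(), after = integer()))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("slider" %in% names(raw) && !"slide" %in% names(raw)) {
    raw <- rename(raw, slide = "slider")
  }
  if (!all(c("before", "slide", "after") %in% names(raw))) {
    abort("slider CSV needs columns before, slide, after")
  }
  make_sliders(raw$before, raw$slide, raw$after, k)
}

#' Read a lever-measurement table from CSV
#'
#' Columns: `specimen`, `digit`, `a` (fulcrum to claw tip), `d` (fulcrum to
#' flexor tubercle), `theta` and `delta` (degrees), `h` (perpendicular
#' tubercle height), `b` (tubercle base-segment length); optional `taxon`
#' and `clade_group`. Lengths must share one physical unit within a file.
#'
#' @param path Path to the CSV file.
#' @return A validated lever tibble.
#' @export
read_levers <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_levers(raw)
}

#' @rdname read_levers
#' @param levers A candidate lever tibble.
#' @export
validate_levers <- function(levers) {
  need <- c("specimen", "a", "d", "theta", "delta", "h", "b")
  miss <- setdiff(need, names(levers))
  if (length(miss) > 0) {
    abort(paste0("lever table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"digit" %in% names(levers)) levers$digit <- "unknown"
  bad <- with(levers, a <= 0 | d <= 0 | b <= 0 | h < 0 |
                theta + delta <= 0 | theta + delta >= 180)
  if (any(bad)) {
    abort(paste0("invalid lever measurements (need a,d,b > 0, h >= 0, ",
                 "0 < theta+delta < 180) for: ",
                 paste(levers$specimen[bad], collapse = ", ")))
  }
  as_tibble(levers)
}
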