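#' Read a cohort of landmark configurations
#'
#' Two formats are supported. TPS: records of the form `LM=n` followed by n
#' coordinate lines, with optional `ID=` and `IMAGE=` lines (`SCALE=` lines
#' are ignored); all records must share one landmark count. CSV: long format
#' with columns `wing_id,label,x,y,cohort,sex`, one row per landmark, rows of
#' one wing contiguous and ordered.
#'
#' TPS files carry no labels, cohort or sex; these are supplied via arguments.
#'
#' @param path input file.
#' @param format `"tps"` or `"csv"` (default: guessed from the extension).
#' @param labels landmark labels for TPS input (default `"p1"`, `"p2"`, ...).
#' @param cohort,sex metadata applied to every TPS record.
#' @param landmark_set landmark set tag for the cohort.
#' @param name cohort name.
#' @return a [wing_cohort]; coordinates are preserved at full precision.
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"),
                           labels = NULL,
                           cohort = "control", sex = "unknown",
                           landmark_set = "SYM10", name = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  configs <- switch(format,
    tps = read_tps_records(path, labels, cohort, sex, landmark_set),
    csv = read_landmark_csv(path, landmark_set))
  wing_cohort(configs, name = name)
}

read_tps_records <- function(path, labels, cohort, sex, landmark_set) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  lm_counts <- integer(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(n) || n < 1L)
      stop(sprintf("record %d: malformed LM= line", r))
    lm_counts[r] <- n
    body <- block[-1L]
    meta <- grepl("^(ID|IMAGE|SCALE)\\s*=", body, ignore.case = TRUE)
    coord_lines <- body[!meta]
    if (length(coord_lines) != n)
      stop(sprintf("record %d: LM=%d but %d coordinate lines",
                   r, n, length(coord_lines)))
    xy <- do.call(rbind, lapply(coord_lines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 2L || any(is.na(v)))
        stop(sprintf("record %d: bad coordinate line '%s'", r, l))
      v
    }))
    id_line <- grep("^ID\\s*=", body, ignore.case = TRUE, value = TRUE)
    wid <- if (length(id_line)) sub("^ID\\s*=\\s*", "", id_line[1L],
                                    ignore.case = TRUE) else sprintf("wing_%d", r)
    lab <- if (is.null(labels)) paste0("p", seq_len(n)) else labels
    if (length(lab) != n)
      stop(sprintf("record %d: %d labels supplied for %d landmarks",
                   r, length(lab), n))
    configs[[r]] <- landmark_config(xy, lab, wing_id = wid, cohort = cohort,
                                    sex = sex, landmark_set = landmark_set)
  }
  if (length(unique(lm_counts)) > 1L) {
    bad <- which(lm_counts != lm_counts[1L])[1L]
    stop(sprintf("record %d has LM=%d, differing from LM=%d of record 1",
                 bad, lm_counts[bad], lm_counts[1L]))
  }
  configs
}

read_landmark_csv <- function(path, landmark_set) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wing_id", "label", "x", "y", "cohort", "sex")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ","))
  ids <- unique(df$wing_id)
  lapply(ids, function(id) {
    sub <- df[df$wing_id == id, , drop = FALSE]
    landmark_config(cbind(sub$x, sub$y), sub$label, wing_id = id,
                    cohort = sub$cohort[1L], sex = sub$sex[1L],
                    landmark_set = landmark_set)
  })
}

#' Write a cohort of landmark configurations
#'
#' Inverse of [read_landmarks()]: coordinates are written with full double
#' precision (17 significant digits) so a read/write round trip is exact.
#'
#' @param cohort a [wing_cohort] (or an empty list, which writes a valid empty
#'   file).
#' @param path output file.
#' @param format `"tps"` or `"csv"`.
#' @export
write_landmarks <- function(cohort, path, format = c("tps", "csv")) {
  format <- match.arg(format)
  configs <- if (inherits(cohort, "wing_cohort")) cohort$configurations
             else if (is.list(cohort)) cohort
             else stop("'cohort' must be a wing_cohort or list")
  if (format == "tps") {
    out <- character(0)
    for (cf in configs) {
      out <- c(out, sprintf("LM=%d", nrow(cf$coords)),
               sprintf("%.17g %.17g", cf$coords[, 1], cf$coords[, 2]),
               sprintf("ID=%s", cf$wing_id))
    }
    writeLines(out, path)
  } else {
    rows <- lapply(configs, function(cf) {
      data.frame(wing_id = cf$wing_id, label = rownames(cf$coords),
                 x = cf$coords[, 1], y = cf$coords[, 2],
                 cohort = cf$cohort, sex = cf$sex, stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(wing_id = character(0), label = character(0),
                          x = numeric(0), y = numeric(0),
                          cohort = character(0), sex = character(0))
    write_csv_full(df, path)
  }
  invisible(NULL)
}

# CSV writer preserving full double precision
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a JSON annotation file
#'
#' Shared annotation schema for disc images:
#' `{"veins": {"L2": [[x,y],...], ...}, "hp_folds": [[x,y],...],
#'  "background_roi": [x,y]}`. Vein entries are polyline click points ordered
#' consistently; `hp_folds` are clicked points on the hinge-pouch folds;
#' `background_roi` is the top-left corner of the square background region.
#'
#' @param path JSON file.
#' @return list with elements `veins` (named list of n x 2 matrices),
#'   `hp_folds` (matrix or NULL), `background_roi` (numeric or NULL).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  veins <- lapply(raw$veins, function(v) {
    m <- as.matrix(v); storage.mode(m) <- "double"
    colnames(m) <- c("x", "y"); m
  })
  hp <- if (!is.null(raw$hp_folds)) {
    m <- as.matrix(raw$hp_folds); storage.mode(m) <- "double"
    colnames(m) <- c("x", "y"); m
  }
  list(veins = veins, hp_folds = hp,
       background_roi = if (!is.null(raw$background_roi))
         as.numeric(raw$background_roi))
}

#' Write a JSON annotation file
#'
#' @param annotations list as returned by [read_annotations()].
#' @param path output JSON file.
#' @export
write_annotations <- function(annotations, path) {
  obj <- list(veins = lapply(annotations$veins, function(m) unname(as.matrix(m))))
  if (!is.null(annotations$hp_folds))
    obj$hp_folds <- unname(as.matrix(annotations$hp_folds))
  if (!is.null(annotations$background_roi))
    obj$background_roi <- annotations$background_roi
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(NULL)
}
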