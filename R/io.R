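prov_header <- function() {
  sprintf("# chromostoch %s",
          as.character(utils::packageVersion("chromostoch")))
}

write_csv_prov <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, sep = ",", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read and write localization tables
#'
#' CSV with header `x_nm,y_nm,frame,channel,precision_nm` (and a
#' provenance comment line).
#'
#' @param locs localization data frame (or a `storm_field`, whose table is
#'   written).
#' @param path file path.
#' @return The table (invisibly for the writer).
#' @export
write_localizations <- function(locs, path) {
  if (inherits(locs, "storm_field")) locs <- locs$locs
  cols <- c("x_nm", "y_nm", "frame", "channel", "precision_nm")
  stopifnot(all(cols %in% names(locs)))
  write_csv_prov(locs[, cols], path)
  invisible(locs)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- read_csv_prov(path)
  if (any(df$precision_nm <= 0)) stop("localization precision must be > 0")
  df
}

#' Read and write ChIP peak tracks as BED6
#'
#' BED6 columns `chrom start end name score strand` with score carrying
#' the peak intensity; coordinates on disk are 0-based half-open, matching
#' the in-memory representation.
#'
#' @param track BED-like data frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @param path file path.
#' @return Data frame with 0-based half-open `start`/`end`.
#' @export
write_track <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end),
    name = track$name %||% paste0("peak_", seq_len(nrow(track))),
    score = track$score %||% 0)
  rtracklayer::export(gr, path, format = "BED")
  invisible(track)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   name = gr$name %||% paste0("peak_", seq_along(gr)),
                   score = gr$score %||% 0,
                   strand = ".")
  df[order(df$chrom, df$start), ]
}

#' Read and write voxel stacks as plain text
#'
#' Simple text container for a 3D stack: a header line
#' `nz ny nx voxel_size_xy voxel_size_z channel` followed by the
#' intensities as an `(nz*ny) x nx` matrix, z-major.
#'
#' @param stack a [voxel_stack()].
#' @param path file path.
#' @return The stack (invisibly for the writer).
#' @export
write_voxel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$intensities)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(), con)
  writeLines(sprintf("%d %d %d %.6g %.6g %s", d[1], d[2], d[3],
                     stack$voxel_size_xy, stack$voxel_size_z,
                     stack$channel), con)
  write.table(matrix(stack$intensities, nrow = d[1] * d[2]), con,
              row.names = FALSE, col.names = FALSE)
  invisible(stack)
}

#' @rdname write_voxel_stack
#' @export
read_voxel_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 5)
  hdr_i <- which(!startsWith(lines, "#"))[1]
  hdr <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]]
  d <- as.integer(hdr[1:3])
  m <- as.matrix(read.table(path, skip = hdr_i, header = FALSE))
  voxel_stack(array(as.numeric(m), dim = d),
              voxel_size_xy = as.numeric(hdr[4]),
              voxel_size_z = as.numeric(hdr[5]), channel = hdr[6])
}

#' Read and write foci tables
#'
#' CSV with columns `cell,channel,x_nm,y_nm,z_nm,n_voxels,intensity`.
#'
#' @param foci foci data frame (a `cell` column is added if absent).
#' @param path file path.
#' @return The table (invisibly for the writer).
#' @export
write_foci <- function(foci, path) {
  if (is.null(foci$cell)) foci$cell <- 1L
  cols <- c("cell", "channel", "x_nm", "y_nm", "z_nm", "n_voxels",
            "intensity")
  write_csv_prov(foci[, cols], path)
  invisible(foci)
}

#' @rdname write_foci
#' @export
read_foci <- function(path) read_csv_prov(path)

#' Write a ground-truth record as JSON
#'
#' @param truth ground-truth list from a generator.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
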