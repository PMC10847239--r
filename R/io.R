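#' Write a cube as an ENVI header + binary pair
#'
#' Writes the standard ENVI layout: a text `.hdr` with dimensions,
#' interleave, wavelength list, and a raw binary file of 32-bit
#' little-endian floats in BSQ, BIL or BIP order.
#'
#' @param cube An [hsi_cube()].
#' @param path Output path without extension; `<path>.hdr` and
#'   `<path>.raw` are created.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  a <- cube$data
  d <- dim(a)  # lines (H), samples (W), bands (B)
  perm <- switch(interleave,
    bsq = c(2, 1, 3),  # fastest: samples, then lines, then bands
    bil = c(2, 3, 1),  # samples, bands, lines
    bip = c(3, 2, 1)   # bands, samples, lines
  )
  vals <- as.numeric(aperm(a, perm))
  hdr <- c(
    "ENVI",
    "description = {fusiondry synthetic cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.6f", cube$wavelengths), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Read an ENVI header + binary pair
#'
#' Supports the basic ENVI dialects written by [write_envi()]: data type 4
#' (float32) or 5 (float64), BSQ/BIL/BIP interleaves, little or big endian,
#' optional wavelength block.
#'
#' @param path Path without extension, or the `.hdr` path.
#' @return An [hsi_cube()].
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!grepl("\\.hdr$", path)) bin_path <- paste0(path, ".raw")
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  field <- function(name) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", name, "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  ns <- as.integer(field("samples")); nl <- as.integer(field("lines"))
  nb <- as.integer(field("bands"))
  dtype <- as.integer(field("data type") %||% "4")
  interleave <- tolower(field("interleave") %||% "bsq")
  byte_order <- as.integer(field("byte order") %||% "0")
  offset <- as.integer(field("header offset") %||% "0")
  wl <- {
    m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
    if (length(m) < 2) seq_len(nb) else as.numeric(strsplit(m[2], ",")[[1]])
  }
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 abort(sprintf("unsupported ENVI data type %d", dtype)))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  vals <- readBin(con, "double", n = ns * nl * nb, size = size,
                  endian = if (byte_order == 0) "little" else "big")
  a <- switch(interleave,
    bsq = aperm(array(vals, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(nb, ns, nl)), c(3, 2, 1)),
    abort(sprintf("unsupported interleave '%s'", interleave))
  )
  hsi_cube(a, wl)
}

#' Write a synthetic dataset to disk
#'
#' Serializes a [generate_dataset()] result the way the acquisition
#' software would: the sample table and E-nose responses as one CSV
#' (`samples.csv`: sample_id, stage_h, mc_true, S1..S10), a ground-truth
#' manifest as YAML, and optionally each cube (with its white/black
#' frames) as ENVI pairs under `cubes/`.
#'
#' @param dataset A `drying_dataset`.
#' @param dir Output directory (created if needed).
#' @param cubes Write the (large) ENVI cubes too?
#' @param interleave ENVI interleave for cubes.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, cubes = FALSE, interleave = "bsq") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- dataset$samples
  write.csv(s[c("sample_id", "stage_h", "mc_true", paste0("S", 1:10))],
            file.path(dir, "samples.csv"), row.names = FALSE)
  yaml::write_yaml(dataset$manifest, file.path(dir, "manifest.yaml"))
  if (cubes) {
    cube_dir <- file.path(dir, "cubes")
    dir.create(cube_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(s))) {
      sim <- dataset_cube(dataset, i)
      stem <- file.path(cube_dir, s$sample_id[i])
      d <- dim(sim$raw$data)
      as_frame <- function(v) {
        hsi_cube(array(rep(v, each = d[1] * d[2]), dim = d),
                 sim$raw$wavelengths)
      }
      write_envi(sim$raw, stem, interleave)
      write_envi(as_frame(sim$white), paste0(stem, "_white"), interleave)
      write_envi(as_frame(sim$black), paste0(stem, "_black"), interleave)
    }
  }
  invisible(dir)
}

#' Read a dataset sample table written by [write_dataset()]
#'
#' @param dir Directory containing `samples.csv` (and `manifest.yaml`).
#' @return A tibble with the sample table; the manifest (if present) is
#'   attached as the `"manifest"` attribute.
#' @export
read_dataset_table <- function(dir) {
  out <- as_tibble(read.csv(file.path(dir, "samples.csv")))
  mf <- file.path(dir, "manifest.yaml")
  if (file.exists(mf)) attr(out, "manifest") <- yaml::read_yaml(mf)
  out
}
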