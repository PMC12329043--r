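#' Read a PLY point cloud
#'
#' Reads ASCII and binary little-endian PLY files (the dialect written by
#' common point-cloud viewers). All vertex properties are kept: `x, y, z`
#' become the coordinate columns, `red, green, blue` (uchar) are rescaled to
#' `[0, 1]`, and any scalar float property (e.g. a correlation `score`) is
#' exposed as a column under its own name.
#'
#' @param path File path.
#' @return A `pointcloud` tibble.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("PLY parse error: unexpected end of header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000) stop("PLY parse error: header too long")
  }
  if (trimws(header[1]) != "ply") {
    stop("PLY parse error at line 1: missing 'ply' magic")
  }
  fmt_line <- grep("^format ", header)
  if (length(fmt_line) != 1) {
    stop("PLY parse error: missing/duplicate format line")
  }
  fmt <- strsplit(trimws(header[fmt_line]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("PLY parse error at line ", fmt_line, ": unsupported format '",
         fmt, "'")
  }

  # parse elements / properties
  elements <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    tok <- strsplit(trimws(header[i]), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  prop_names = character(), prop_types = character(),
                  line = i)
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$prop_types <- c(cur$prop_types, paste("list", tok[3], tok[4]))
        cur$prop_names <- c(cur$prop_names, tok[5])
      } else {
        cur$prop_types <- c(cur$prop_types, tok[2])
        cur$prop_names <- c(cur$prop_names, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!"vertex" %in% names(elements)) {
    stop("PLY parse error: no 'vertex' element")
  }
  vert <- elements$vertex
  nv <- vert$count
  np <- length(vert$prop_names)

  if (fmt == "ascii") {
    vals <- if (nv > 0) {
      lines <- readLines(con, n = nv)
      if (length(lines) < nv) {
        stop("PLY parse error at line ",
             length(header) + length(lines) + 1,
             ": expected ", nv, " vertices, found ", length(lines))
      }
      sp <- strsplit(trimws(lines), "\\s+")
      bad <- which(lengths(sp) != np)
      if (length(bad)) {
        stop("PLY parse error at line ", length(header) + bad[1],
             ": expected ", np, " values")
      }
      matrix(as.numeric(unlist(sp)), nv, np, byrow = TRUE)
    } else matrix(numeric(), 0, np)
  } else {
    # binary little-endian; vertex element assumed first data block
    type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)
    if (any(startsWith(vert$prop_types, "list"))) {
      stop("PLY parse error: list properties on vertices unsupported")
    }
    sizes <- type_size[vert$prop_types]
    if (anyNA(sizes)) stop("PLY parse error: unknown property type")
    vals <- matrix(0, nv, np)
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = rec * nv)
    if (length(raw) < rec * nv) {
      stop("PLY parse error: truncated binary vertex data")
    }
    offs <- cumsum(c(0, sizes[-np]))
    for (j in seq_len(np)) {
      idx <- as.vector(outer(seq_len(sizes[j]),
                             (seq_len(nv) - 1) * rec + offs[j], "+"))
      bytes <- raw[idx]
      tp <- vert$prop_types[j]
      vals[, j] <- switch(
        tp,
        float = , float32 = readBin(bytes, "double", n = nv, size = 4,
                                    endian = "little"),
        double = , float64 = readBin(bytes, "double", n = nv, size = 8,
                                     endian = "little"),
        uchar = , uint8 = as.numeric(readBin(bytes, "integer", n = nv,
                                             size = 1, signed = FALSE,
                                             endian = "little")),
        char = , int8 = as.numeric(readBin(bytes, "integer", n = nv,
                                           size = 1, signed = TRUE,
                                           endian = "little")),
        short = , int16 = as.numeric(readBin(bytes, "integer", n = nv,
                                             size = 2, signed = TRUE,
                                             endian = "little")),
        ushort = , uint16 = as.numeric(readBin(bytes, "integer", n = nv,
                                               size = 2, signed = FALSE,
                                               endian = "little")),
        int = , int32 = , uint = , uint32 =
          as.numeric(readBin(bytes, "integer", n = nv, size = 4,
                             endian = "little")),
        stop("PLY parse error: unknown property type ", tp))
    }
  }

  colnames(vals) <- vert$prop_names
  df <- tibble::as_tibble(as.data.frame(vals))
  for (ch in c("red", "green", "blue")) {
    if (ch %in% names(df) &&
        vert$prop_types[match(ch, vert$prop_names)] %in%
        c("uchar", "uint8")) {
      df[[ch]] <- df[[ch]] / 255
    }
  }
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("PLY parse error: vertex element lacks x/y/z properties")
  }
  as_pointcloud(df)
}

#' Write a point cloud as ASCII PLY
#'
#' Emits `x, y, z` as float properties, optional `red, green, blue` as
#' uchar, and a `score` float property when present — so correlation
#' thresholds remain reproducible on the exported cloud in external viewers.
#'
#' @param cloud Cloud tibble with `x, y, z` and optional `score`,
#'   `red/green/blue` columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  n <- nrow(cloud)
  has_col <- all(c("red", "green", "blue") %in% names(cloud))
  has_score <- "score" %in% names(cloud)
  header <- c(
    "ply", "format ascii 1.0",
    "comment telestereo point cloud (mm)",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_col) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    if (has_score) "property float score",
    "end_header")
  body <- character(0)
  if (n > 0) {
    parts <- list(sprintf("%.8g %.8g %.8g", cloud$x, cloud$y, cloud$z))
    if (has_col) {
      parts <- c(parts, list(sprintf("%d %d %d",
                                     as.integer(round(cloud$red * 255)),
                                     as.integer(round(cloud$green * 255)),
                                     as.integer(round(cloud$blue * 255)))))
    }
    if (has_score) parts <- c(parts, list(sprintf("%.6f", cloud$score)))
    body <- do.call(paste, parts)
  }
  writeLines(c(header, body), path)
  invisible(path)
}
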