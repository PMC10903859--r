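# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures ship with the package.

# centered digital disk on an n x n frame (pixel-center criterion)
mkdisk <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  y <- row(matrix(0, n, n)) - cy
  x <- col(matrix(0, n, n)) - cx
  x^2 + y^2 <= r^2
}

mkmask <- function(px, scale = 1, semantics = "sample") {
  binary_mask(px, scale, semantics = semantics)
}

empty_mask <- function(n, scale = 1) mkmask(matrix(FALSE, n, n), scale)

# small synthetic slice for unit tests (fast: ~0.3 s)
test_params <- function(...) {
  defaults <- list(frame = c(256L, 256L), sample_axes = c(230, 200),
                   n_ducts = 2L, duct_radius_range = c(30, 50),
                   wall_thickness = 30)
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# polygonal circle approximation (0-based pixel coordinates)
circle_poly <- function(cx, cy, r, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# brute-force pixel-center point-in-polygon oracle (even-odd + on-edge)
oracle_point_in_polygon <- function(v, H, W) {
  out <- matrix(FALSE, H, W)
  n <- nrow(v)
  for (py in 0:(H - 1)) for (px in 0:(W - 1)) {
    inside <- FALSE; onedge <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[j, 1]; by <- v[j, 2]
      if ((ay > py) != (by > py)) {
        xi <- ax + (py - ay) / (by - ay) * (bx - ax)
        if (px < xi) inside <- !inside
      }
      dx <- bx - ax; dy <- by - ay; l2 <- dx^2 + dy^2
      if (l2 > 1e-12) {
        t <- max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / l2))
        if ((ax + t * dx - px)^2 + (ay + t * dy - py)^2 < 1e-9) onedge <- TRUE
      }
    }
    if (inside || onedge) out[py + 1L, px + 1L] <- TRUE
  }
  out
}

# --- minimal stored-entry ZIP writer (for ImageJ .zip import tests) ---
crc32_table <- local({
  tb <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L)) bitwXor(bitwShiftR(c, 1L), -306674912L) else
        bitwShiftR(c, 1L)
    tb[i + 1] <- c
  }
  tb
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(bitwShiftR(c, 8L) ,
                 crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# files: named list of raw vectors; writes an uncompressed zip archive
make_zip_stored <- function(files, out) {
  local_parts <- list(); central_parts <- list(); offset <- 0L
  for (nm in names(files)) {
    data <- files[[nm]]
    name <- charToRaw(nm)
    crc <- crc32(data)
    lh <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
            u16(0), u16(0), u32(crc), u32(length(data)), u32(length(data)),
            u16(length(name)), u16(0), name, data)
    ch <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0),
            u16(0), u16(0), u16(0), u32(crc), u32(length(data)),
            u32(length(data)), u16(length(name)), u16(0), u16(0), u16(0),
            u16(0), u32(0), u32(offset), name)
    local_parts[[nm]] <- lh
    central_parts[[nm]] <- ch
    offset <- offset + length(lh)
  }
  central <- do.call(c, central_parts)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(files)), u16(length(files)), u32(length(central)),
            u32(offset), u16(0))
  writeBin(c(do.call(c, local_parts), central, eocd), out)
  invisible(out)
}

# bytes of a minimal ImageJ polygon .roi (corner-grid coordinates)
make_ijroi_polygon <- function(xs, ys) {
  be16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "big")
  n <- length(xs)
  top <- min(ys); left <- min(xs)
  hdr <- raw(64)
  hdr[1:4] <- charToRaw("Iout")
  hdr[5:6] <- be16(227)              # version
  hdr[7] <- as.raw(0L)               # type: polygon
  hdr[9:10] <- be16(top); hdr[11:12] <- be16(left)
  hdr[13:14] <- be16(max(ys)); hdr[15:16] <- be16(max(xs))
  hdr[17:18] <- be16(n)
  coords <- c(do.call(c, lapply(xs - left, be16)),
              do.call(c, lapply(ys - top, be16)))
  c(hdr, coords)
}
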