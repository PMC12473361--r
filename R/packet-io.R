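# Decoding/encoding of the headband's framed Bluetooth capture format and
# tabular signal I/O.
#
# Wire layout of one packet:
#   start byte 0x68 | payload length (2-byte integer) | function code (1 byte,
#   0x27 = left-hemisphere stream) | payload (4 bytes per sample, signed ADC
#   words) | CRC (2 bytes) | end byte 0x16
#
# The device documentation does not fix the CRC algorithm, byte order or the
# ADC-to-ohm scale, so all three are configuration, not guesses baked into the
# decoder.

PKT_START <- 0x68L
PKT_END <- 0x16L
PKT_FUNCTION_LEFT <- 0x27L

#' Packet format configuration
#'
#' Bundles the configurable aspects of the capture wire format: integer byte
#' order, CRC algorithm parameters, and which bytes the CRC covers. Defaults
#' are little-endian integers and CRC-16/CCITT-FALSE (polynomial `0x1021`,
#' initial value `0xFFFF`) computed over the function code and payload.
#'
#' @param endian `"little"` or `"big"`, applied to the length field, samples
#'   and CRC alike.
#' @param crc_poly,crc_init CRC-16 polynomial and initial register value.
#' @param crc_over which bytes the checksum covers: from the function code
#'   through the payload (default) or from the length field through the
#'   payload.
#' @return A list of class `packet_config`.
#' @export
packet_config <- function(endian = c("little", "big"),
                          crc_poly = 0x1021, crc_init = 0xFFFF,
                          crc_over = c("function_payload", "length_payload")) {
  structure(
    list(endian = match.arg(endian), crc_poly = as.integer(crc_poly),
         crc_init = as.integer(crc_init), crc_over = match.arg(crc_over)),
    class = "packet_config"
  )
}

# Table-driven CRC-16 (non-reflected). Table cached per polynomial.
crc16_table_env <- new.env(parent = emptyenv())

crc16_table <- function(poly) {
  key <- sprintf("p%04x", poly)
  tab <- crc16_table_env[[key]]
  if (is.null(tab)) {
    tab <- integer(256)
    for (i in 0:255) {
      crc <- bitwShiftL(i, 8)
      for (j in 1:8) {
        crc <- if (bitwAnd(crc, 0x8000L) != 0L) {
          bitwAnd(bitwXor(bitwShiftL(crc, 1), poly), 0xFFFFL)
        } else {
          bitwAnd(bitwShiftL(crc, 1), 0xFFFFL)
        }
      }
      tab[i + 1L] <- crc
    }
    crc16_table_env[[key]] <- tab
  }
  tab
}

crc16 <- function(bytes, poly = 0x1021, init = 0xFFFF) {
  tab <- crc16_table(as.integer(poly))
  crc <- as.integer(init)
  for (b in as.integer(bytes)) {
    idx <- bitwXor(bitwShiftR(crc, 8), b)
    crc <- bitwAnd(bitwXor(bitwShiftL(crc, 8), tab[idx + 1L]), 0xFFFFL)
  }
  crc
}

bytes_to_uint <- function(bytes, endian) {
  if (endian == "big") bytes <- rev(bytes)
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

uint_to_bytes <- function(x, n, endian) {
  b <- integer(n)
  x <- as.numeric(x)
  for (i in seq_len(n)) {
    b[i] <- as.integer(x %% 256)
    x <- x %/% 256
  }
  if (endian == "big") rev(b) else b
}

decode_samples <- function(payload, endian) {
  if (length(payload) == 0) return(numeric(0))
  m <- matrix(as.numeric(payload), nrow = 4)
  if (endian == "big") m <- m[4:1, , drop = FALSE]
  v <- colSums(m * 256^(0:3))
  ifelse(v >= 2^31, v - 2^32, v)  # 32-bit two's complement
}

encode_samples <- function(samples, endian) {
  if (length(samples) == 0) return(integer(0))
  v <- as.numeric(samples)
  v <- ifelse(v < 0, v + 2^32, v)
  m <- vapply(0:3, function(k) as.integer((v %/% 256^k) %% 256), integer(length(v)))
  m <- matrix(t(m), nrow = 4)  # rows = byte index (little-endian order)
  if (endian == "big") m <- m[4:1, , drop = FALSE]
  as.integer(m)
}

crc_region <- function(bytes, n_payload, config) {
  from <- if (config$crc_over == "function_payload") 4L else 2L
  bytes[from:(4L + n_payload)]
}

#' Parse one framed capture packet
#'
#' Decodes a single packet from its wire bytes. Framing violations (wrong
#' start/end byte, length inconsistent with the byte count) raise an error
#' identifying the byte offset; a checksum mismatch does not — the packet is
#' returned with `valid = FALSE` so callers can decide how to treat it.
#'
#' @param raw A raw vector or integer vector of byte values.
#' @param config A [packet_config()].
#' @return A list of class `reg_packet` with fields `function_code`,
#'   `sample_count`, `samples` (signed 32-bit ADC words), `crc` (stored
#'   checksum) and `valid`.
#' @examples
#' pkt <- encode_packet(new_packet(c(212200, 212195)))
#' parse_packet(pkt)
#' @export
parse_packet <- function(raw, config = packet_config()) {
  b <- as.integer(raw)
  if (length(b) == 0) abort("empty packet")
  if (b[1] != PKT_START) {
    abort(sprintf("framing error at byte offset 0: expected start byte 0x68, got 0x%02x", b[1]))
  }
  if (length(b) < 7) abort(sprintf("framing error: packet truncated (%d bytes < 7-byte minimum)", length(b)))
  n_payload <- bytes_to_uint(b[2:3], config$endian)
  if (n_payload %% 4 != 0) {
    abort(sprintf("framing error at byte offset 1: payload length %d is not a multiple of 4", n_payload))
  }
  total <- 7 + n_payload
  if (length(b) != total) {
    abort(sprintf("framing error: length field implies %d bytes, got %d", total, length(b)))
  }
  if (b[total] != PKT_END) {
    abort(sprintf("framing error at byte offset %d: expected end byte 0x16, got 0x%02x", total - 1, b[total]))
  }
  payload <- if (n_payload > 0) b[5:(4 + n_payload)] else integer(0)
  stored_crc <- bytes_to_uint(b[(5 + n_payload):(6 + n_payload)], config$endian)
  calc_crc <- crc16(crc_region(b, n_payload, config), config$crc_poly, config$crc_init)
  structure(
    list(function_code = b[4], sample_count = n_payload %/% 4L,
         samples = decode_samples(payload, config$endian),
         crc = as.integer(stored_crc), valid = stored_crc == calc_crc),
    class = "reg_packet"
  )
}

#' Construct a packet record from samples
#'
#' @param samples Signed 32-bit ADC impedance words.
#' @param function_code Packet function code byte (default `0x27`, the
#'   left-hemisphere stream).
#' @return A `reg_packet` record (with `crc`/`valid` unset until encoded).
#' @export
new_packet <- function(samples, function_code = PKT_FUNCTION_LEFT) {
  structure(
    list(function_code = as.integer(function_code),
         sample_count = length(samples), samples = as.numeric(samples),
         crc = NA_integer_, valid = NA),
    class = "reg_packet"
  )
}

#' @export
print.reg_packet <- function(x, ...) {
  cat(sprintf("<reg_packet> function 0x%02x, %d sample(s), crc %s, valid: %s\n",
              x$function_code, x$sample_count,
              if (is.na(x$crc)) "unset" else sprintf("0x%04x", x$crc), x$valid))
  invisible(x)
}

#' Encode a packet record to wire bytes
#'
#' Inverse of [parse_packet()]: `parse_packet(encode_packet(rec))` reproduces
#' `rec` field for field with a valid checksum.
#'
#' @inheritParams parse_packet
#' @param rec A `reg_packet` (from [new_packet()] or [parse_packet()]).
#' @return A raw vector.
#' @export
encode_packet <- function(rec, config = packet_config()) {
  if (rec$sample_count != length(rec$samples)) {
    abort("sample_count does not match the number of samples")
  }
  payload <- encode_samples(rec$samples, config$endian)
  n_payload <- length(payload)
  head_bytes <- c(PKT_START, uint_to_bytes(n_payload, 2, config$endian),
                  as.integer(rec$function_code), payload)
  crc <- crc16(crc_region(head_bytes, n_payload, config), config$crc_poly, config$crc_init)
  as.raw(c(head_bytes, uint_to_bytes(crc, 2, config$endian), PKT_END))
}

#' Read a hex-text capture file into an impedance series
#'
#' Capture files hold the raw byte stream as hexadecimal text (whitespace and
#' newlines tolerated). Samples from consecutive valid packets are
#' concatenated in order; packets with a failed checksum or broken framing are
#' skipped with a message, so isolated glitches do not abort a long recording.
#'
#' @param x Path to a capture file, or a character scalar of hex text.
#' @param scale Ohms per raw ADC unit (device calibration; default 0.001).
#' @param fs Sampling rate in Hz (default 200).
#' @param config A [packet_config()].
#' @return A tibble with columns `time_s` and `z` (impedance, ohms), timestamps
#'   assigned at `1/fs` spacing from zero. The number of skipped packets is
#'   attached as attribute `skipped`.
#' @export
read_capture <- function(x, scale = 0.001, fs = 200, config = packet_config()) {
  assert_scalar_pos(scale, "scale")
  assert_scalar_pos(fs, "fs")
  txt <- if (length(x) == 1 && file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "") else paste(x, collapse = "")
  hex <- gsub("[^0-9a-fA-F]", "", txt)
  if (nchar(hex) == 0) abort("no hex data found in capture input")
  if (nchar(hex) %% 2 != 0) abort("odd number of hex characters in capture input")
  b <- strtoi(substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2)), base = 16L)

  samples <- list()
  skipped <- 0L
  i <- 1L
  n <- length(b)
  while (i <= n) {
    if (b[i] != PKT_START) {
      i <- i + 1L
      next
    }
    frame <- NULL
    if (i + 6 <= n) {
      n_payload <- bytes_to_uint(b[(i + 1):(i + 2)], config$endian)
      total <- 7 + n_payload
      if (n_payload %% 4 == 0 && i + total - 1 <= n && b[i + total - 1] == PKT_END) {
        frame <- b[i:(i + total - 1)]
      }
    }
    if (is.null(frame)) {
      # not a decodable frame at this 0x68; resynchronize one byte on
      i <- i + 1L
      next
    }
    pkt <- parse_packet(frame, config)
    if (isTRUE(pkt$valid)) {
      samples[[length(samples) + 1L]] <- pkt$samples
    } else {
      skipped <- skipped + 1L
      inform(sprintf("skipping packet at byte offset %d: checksum mismatch", i - 1L))
    }
    i <- i + length(frame)
  }
  z_raw <- unlist(samples) %||% numeric(0)
  if (length(z_raw) == 0) abort("no valid packets found in capture input")
  out <- tibble(time_s = (seq_along(z_raw) - 1) / fs, z = z_raw * scale)
  attr(out, "skipped") <- skipped
  out
}
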