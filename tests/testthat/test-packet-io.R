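test_that("CRC implementation matches an independent bitwise oracle", {
  # published check value for CRC-16/CCITT-FALSE
  expect_identical(regcar:::crc16(utf8ToInt("123456789")), 0x29B1L)
  withr::with_seed(11, {
    for (i in 1:20) {
      bytes <- sample(0:255, sample(1:40, 1), replace = TRUE)
      expect_identical(regcar:::crc16(bytes), crc16_oracle(bytes))
    }
  })
})

test_that("well-formed packets parse to the declared layout", {
  pkt <- encode_packet(new_packet(212200, function_code = 0x27))
  rec <- parse_packet(pkt)
  expect_equal(rec$function_code, 0x27)
  expect_equal(rec$sample_count, 1)
  expect_equal(rec$samples, 212200)
  expect_true(rec$valid)
  # frame size: 1 start + 2 length + 1 function + 4*CNT + 2 crc + 1 end
  expect_length(encode_packet(new_packet(c(1, 2, 3))), 7 + 12)
  # empty payload
  rec0 <- parse_packet(encode_packet(new_packet(numeric(0))))
  expect_equal(rec0$sample_count, 0)
  expect_length(rec0$samples, 0)
  expect_true(rec0$valid)
})

test_that("encode/parse round-trips over random payloads, both endiannesses", {
  withr::with_seed(12, {
    for (endian in c("little", "big")) {
      cfg <- packet_config(endian = endian)
      for (i in 1:15) {
        samples <- sample(c(-2^31, -1, 0, 1, 2^31 - 1,
                            round(runif(8, -1e9, 1e9))), sample(0:6, 1))
        rec <- new_packet(samples)
        back <- parse_packet(encode_packet(rec, cfg), cfg)
        expect_equal(back$samples, as.numeric(samples))
        expect_equal(back$sample_count, length(samples))
        expect_true(back$valid)
        expect_identical(encode_packet(back, cfg), encode_packet(rec, cfg))
      }
    }
  })
})

test_that("a flipped payload bit invalidates the checksum without dropping samples", {
  pkt <- as.integer(encode_packet(new_packet(c(100, 200))))
  pkt[6] <- bitwXor(pkt[6], 0x01L)  # payload byte
  rec <- parse_packet(pkt)
  expect_false(rec$valid)
  expect_length(rec$samples, 2)
  # oracle confirms the mismatch
  expect_false(rec$crc == crc16_oracle(pkt[4:12]))
})

test_that("framing violations raise errors naming the byte offset", {
  good <- as.integer(encode_packet(new_packet(c(1, 2))))
  bad_start <- good; bad_start[1] <- 0x69L
  expect_error(parse_packet(bad_start), "offset 0")
  bad_end <- good; bad_end[length(good)] <- 0x00L
  expect_error(parse_packet(bad_end), "end byte")
  expect_error(parse_packet(good[-length(good)]), "framing")
  expect_error(encode_packet(list(sample_count = 2, samples = 1:3)), "sample_count")
})

test_that("read_capture concatenates valid packets and skips corrupt ones", {
  packets <- lapply(1:10, function(i) encode_packet(new_packet(1000 * i + 1:5)))
  hex <- raw_to_hex(unlist(packets))
  reg <- read_capture(hex, scale = 0.001, fs = 200)
  expect_equal(nrow(reg), 50)
  expect_equal(max(reg$time_s), 49 / 200)
  expect_equal(attr(reg, "skipped"), 0L)
  # sample count equals the sum of CNT over valid packets; scale applied
  expect_equal(reg$z[1], 1001 * 0.001)

  # corrupt one packet's payload -> its 5 samples skipped, one message
  stream <- as.integer(unlist(packets))
  stream[2 * 27 + 6] <- bitwXor(stream[2 * 27 + 6], 0x10L)  # inside packet 3
  expect_message(
    reg2 <- read_capture(raw_to_hex(as.raw(stream))),
    "checksum mismatch"
  )
  expect_equal(nrow(reg2), 45)
  expect_equal(attr(reg2, "skipped"), 1L)

  expect_error(suppressMessages(read_capture("68 00")), "hex|valid")
})

test_that("raw ADC words scale to ohms as configured", {
  reg <- read_capture(raw_to_hex(encode_packet(new_packet(212200))), scale = 0.001)
  expect_equal(reg$z, 212.2)
})

test_that("signal CSV round-trips bit-stably", {
  x <- tibble::tibble(time_s = (0:99) / 200, z = 212.2 + sin(1:100) * pi * 1e-3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(x, path)
  expect_identical(readLines(path)[1], "time_s,value")
  back <- read_signal_csv(path, value_col = "z")
  expect_identical(back$z, x$z)
  expect_identical(back$time_s, x$time_s)
})

test_that("align_series crops to the common interval and pairs nearest samples", {
  fs <- 200
  reg <- tibble::tibble(time_s = (0:999) / fs, z = rnorm(1000))
  bp <- tibble::tibble(time_s = (0:999) / fs, p = rnorm(1000))
  same <- align_series(reg, bp)
  expect_identical(same$reg, reg)
  expect_identical(same$bp, bp)

  # bp shifted +0.4 s: cropped to the overlap, reg start advances by 0.4 s
  bp_shift <- dplyr::mutate(bp, time_s = time_s + 0.4)
  out <- align_series(reg, bp_shift)
  expect_equal(min(out$reg$time_s), 0.4)
  expect_equal(max(out$reg$time_s), max(reg$time_s))
  expect_equal(out$bp$time_s, out$reg$time_s)   # same grid once cropped
  expect_equal(nrow(out$reg), nrow(out$bp))

  # sub-sample 2 ms offset: pairing shifts by at most one sample
  bp_2ms <- dplyr::mutate(bp, time_s = time_s + 0.002)
  out2 <- align_series(reg, bp_2ms)
  offs <- abs(out2$bp$time_s - out2$reg$time_s)
  expect_true(all(offs <= 0.5 / fs + 1e-12))
  # no extrapolation: outputs are subsets of inputs
  expect_true(all(out2$bp$time_s %in% bp_2ms$time_s))
  expect_true(all(out2$reg$time_s %in% reg$time_s))

  expect_error(align_series(reg, dplyr::mutate(bp, time_s = time_s + 100)), "overlap")
})
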