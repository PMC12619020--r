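## Shared constants, loaded before every other source file.

## the nine sensor stream names recognised throughout the package
PUT_STREAMS <- c("activity", "battery", "bluetooth", "calls", "location",
                 "screen", "wifi", "sleep", "steps")

## half-open within-day epoch windows, seconds since local midnight
EPOCH_BOUNDS <- list(
  night     = c(0, 21600),
  morning   = c(21600, 43200),
  afternoon = c(43200, 64800),
  evening   = c(64800, 86400),
  all_day   = c(0, 86400)
)

EPOCH_NAMES <- names(EPOCH_BOUNDS)
SUB_EPOCHS <- c("night", "morning", "afternoon", "evening")
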