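# Channel and feature-slot naming shared across modules. Defined first in
# collation order because other files build derived constants at load time.

DEVICE_CHANNELS <- c("ppg_green", "ppg_red", "ppg_ir", "bioz", "ssecg")
PULSATILE_CHANNELS <- c("ppg_green", "ppg_red", "ppg_ir", "bioz")

# 14 breathing-rate feature slots: BW from the pulsatile channels only (no
# baseline wander exists on the upper-arm ECG), AM and FM from all five.
BR_SLOTS <- c(paste0("bw_", PULSATILE_CHANNELS),
              paste0("am_", c(PULSATILE_CHANNELS, "ssecg")),
              paste0("fm_", c(PULSATILE_CHANNELS, "ssecg")))
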