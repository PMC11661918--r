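# Frozen byte-level oracle fixtures generated with independent
# reference codecs (Pillow for PNG, nibabel for NIfTI-1); hex-encoded.

hex_to_raw <- function(h) as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))

fixture_png_rgb_hex <- "89504e470d0a1a0a0000000d49484452000000030000000208020000001216f14d0000001449444154789c6364e01291030396a8a828080b0016bc029a92e8954f0000000049454e44ae426082"
# 2 x 3 RGB, pixel (i,j,c) value = ((i-1)*3*3 + (j-1)*3 + (c-1)) * 10 / 255

fixture_png_mask_hex <- "89504e470d0a1a0a0000000d49484452000000030000000408000000006e46dadb0000001849444154789c63646064646266fccfc0c0c0ccc2c8c800000999011252da43510000000049454e44ae426082"
# 4 x 3 grayscale labels: rows (0,1,2), (3,2,1), (0,0,3), (1,2,3)

fixture_nii_hex <- "5c0100000000000000000000000000000000000000000000000000000000000000000000000000000300020003000400010001000100010000000000000000000000000000001000200000000000803f0000803f0000803f0000803f0000803f0000803f0000803f0000803f0000b0430000803f00000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000002000000000000000000000000000000000000000000000000000000803f000000000000000000000000000000000000803f000000000000000000000000000000000000803f00000000000000000000000000000000000000006e2b310000000000000000000000803e0000003f0000403f0000803f0000a03f0000c03f0000e03f0000004000001040000020400000304000004040000050400000604000007040000080400000884000009040000098400000a0400000a8400000b0400000b840"
# 2 x 3 x 4 float32 volume, column-major values 0, 0.25, ..., 5.75
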