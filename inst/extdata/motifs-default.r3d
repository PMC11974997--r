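# Default RNA 3D motif descriptor set: 51 recurrent motif architectures
# curated in-house from the RNA 3D motif literature (tetraloop, K-turn,
# loop E, C-loop, junction and branch-segment families). Consensus strings
# are IUPAC RNA codes; '-' denotes an empty segment. One record per line:
#   name TYPE key=value ...
# Types and segment roles:
#   HL left1..left4 / loop / right1..right4   (correlated left/right pairs)
#   BL flank5 / loop / flank3
#   IL outerL loopL innerL innerR loopR outerR
#   J3 s1 s2 s3        J4 s1 s2 s3 s4        BS seg
# This set expands to 96 variant models (HL 1, BL 2, IL 2, J3 3, J4 4, BS 1
# variants per motif).
#
# --- hairpin-loop motifs (15) ---
GNRA         HL left1=G loop=N right1=RA
UNCG         HL left1=U loop=NC right1=G
CUUG         HL left1=C loop=UU right1=G
T-loop       HL left1=U loop=UCRAN right1=Y
U-turn       HL left1=U loop=NR right1=-
GAGAU        HL left1=G loop=AGA right1=U
CsrA-box     HL left1=A loop=GGA right1=U
AGNN         HL left1=A loop=GN right1=N
Anticodon    HL left1=CU loop=NNN right1=AG
s2m-loop     HL left1=C loop=GNUA right1=G
GANC         HL left1=G loop=AN right1=C
A-rich-loop  HL left1=- loop=AAAA right1=-
UGAA         HL left1=U loop=GA right1=A
UUAA         HL left1=U loop=UA right1=A
ANYA         HL left1=A loop=NY right1=A
#
# --- bulge motifs (3) ---
Docking-elbow BL flank5=U loop=AA flank3=-
A-bulge       BL flank5=- loop=A flank3=-
UNR-bulge     BL flank5=- loop=UNR flank3=-
#
# --- internal-loop motifs (23) ---
K-turn        IL outerL=GA loopL=- innerL=- innerR=- loopR=RNN outerR=AG
K-turn-b      IL outerL=GA loopL=- innerL=- innerR=- loopR=RN outerR=AG
C-loop        IL outerL=- loopL=CNC innerL=- innerR=- loopR=ANRA outerR=-
Loop-E        IL outerL=AGUA loopL=- innerL=- innerR=- loopR=GAUG outerR=-
G-bulge       IL outerL=G loopL=- innerL=- innerR=- loopR=NG outerR=-
pK-turn       IL outerL=GA loopL=- innerL=- innerR=- loopR=NNN outerR=AG
Hook-turn     IL outerL=- loopL=UGG innerL=- innerR=- loopR=AA outerR=-
J4a-4b        IL outerL=- loopL=AGUG innerL=- innerR=- loopR=GAA outerR=-
Sarcin-ricin  IL outerL=- loopL=GUA innerL=G innerR=A loopR=GAA outerR=-
Tandem-GA     IL outerL=GA loopL=- innerL=- innerR=- loopR=- outerR=AG
UAA-GAN       IL outerL=- loopL=UAA innerL=- innerR=- loopR=GAN outerR=-
Bulged-G      IL outerL=- loopL=AUG innerL=- innerR=- loopR=GUA outerR=-
Right-angle   IL outerL=- loopL=CUG innerL=- innerR=- loopR=AG outerR=-
S-turn        IL outerL=- loopL=GUA innerL=- innerR=- loopR=AA outerR=-
Twist-up      IL outerL=- loopL=UA innerL=- innerR=- loopR=GGA outerR=-
Rope-sway     IL outerL=- loopL=GCUC innerL=- innerR=- loopR=AGC outerR=-
Tandem-sheared IL outerL=AG loopL=- innerL=- innerR=- loopR=- outerR=GA
1x1-AG        IL outerL=- loopL=A innerL=- innerR=- loopR=G outerR=-
2x2-GA        IL outerL=- loopL=GA innerL=- innerR=- loopR=AG outerR=-
Single-U      IL outerL=- loopL=U innerL=- innerR=- loopR=- outerR=-
Pi-turn       IL outerL=- loopL=AUU innerL=- innerR=- loopR=GA outerR=-
Omega-turn    IL outerL=- loopL=CAA innerL=- innerR=- loopR=UG outerR=-
A-minor-IL    IL outerL=- loopL=AA innerL=- innerR=- loopR=- outerR=-
#
# --- 3-way junction motifs (5) ---
Hammerhead-J3 J3 s1=CUGA s2=GA s3=AA
TPP-J3        J3 s1=CUG s2=AG s3=-
J3-groupII    J3 s1=AGC s2=GA s3=-
Alpha-J3      J3 s1=UAA s2=A s3=-
RNaseP-J3     J3 s1=GGU s2=AA s3=A
#
# --- 4-way junction motifs (3) ---
HCV-IRES-J4   J4 s1=- s2=AG s3=- s4=U
U1-J4         J4 s1=A s2=- s3=UG s4=-
tRNA-J4       J4 s1=U s2=GG s3=- s4=C
#
# --- branch-segment motifs (2) ---
T-loop-domain BS seg=UUCRA
CRC-box       BS seg=GAAC
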