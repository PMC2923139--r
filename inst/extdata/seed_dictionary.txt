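# problem words over the degenerate alphabet, one per line
a
abstract
add
and
ant
art
as
assay
assays
at
band
bands
bad
bat
brand
brands
by
can
cash
catch
data
dark
day
days
draw
dry
gas
grab
gram
grams
grand
grant
grants
gray
had
hand
hands
has
man
many
mass
match
may
sand
say
smart
standard
standards
start
starts
stay
strand
strands
than
that
thaw
want
wants
was
wash
way
ways
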