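a
an
the
and
or
of
in
on
at
to
for
with
by
from
is
are
was
were
be
been
has
have
had
do
does
did
you
your
i
my
me
he
she
it
its
his
her
they
them
their
this
that
these
those
any
some
no
not
there
ever
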